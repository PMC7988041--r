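#' Create a subject record
#'
#' One study participant as a one-row tibble: group, compartment volumes,
#' aqueduct geometry, baseline pressure and (optionally) a measured
#' intracranial pressure.
#'
#' @param id Subject label.
#' @param group `"healthy"` or `"patient"`.
#' @param ventricular_volume_ml,brain_volume_ml,sas_volume_ml Compartment
#'   volumes in ml.
#' @param aqueduct_radius_m Aqueduct radius in m (must lie in 0.5-3 mm).
#' @param aqueduct_length_m Aqueduct length in m (default 15 mm).
#' @param baseline_pressure_pa Baseline pressure in Pa; defaults to the
#'   group outlet pressure (500 / 2700 Pa).
#' @param measured_icp_pa Optional measured intracranial pressure, Pa.
#' @return One-row tibble of class `csf_subject`.
#' @export
subject_record <- function(id, group = c("healthy", "patient"),
                           ventricular_volume_ml = if (group == "healthy") 20.3 else 281.6,
                           brain_volume_ml = if (group == "healthy") 1297.0 else 1071.7,
                           sas_volume_ml = if (group == "healthy") 105.9 else 108.4,
                           aqueduct_radius_m = if (group == "healthy") 1.0e-3 else 1.5e-3,
                           aqueduct_length_m = 15e-3,
                           baseline_pressure_pa = NULL,
                           measured_icp_pa = NA_real_) {
  group <- match.arg(group)
  check_number(ventricular_volume_ml, "ventricular_volume_ml", lower = 0, strict_lower = TRUE)
  check_number(aqueduct_radius_m, "aqueduct_radius_m", lower = 0.5e-3, upper = 3e-3)
  check_number(aqueduct_length_m, "aqueduct_length_m", lower = 0, strict_lower = TRUE)
  baseline_pressure_pa <- baseline_pressure_pa %||% outlet_pressure(group)
  out <- tibble(
    id = as.character(id), group = group,
    ventricular_volume_ml = ventricular_volume_ml,
    brain_volume_ml = brain_volume_ml, sas_volume_ml = sas_volume_ml,
    aqueduct_radius_m = aqueduct_radius_m,
    aqueduct_length_m = aqueduct_length_m,
    baseline_pressure_pa = baseline_pressure_pa,
    measured_icp_pa = measured_icp_pa
  )
  class(out) <- c("csf_subject", class(out))
  out
}

#' Solver options for the reduced-order network
#'
#' @param sas_compliance Constant subarachnoid-space compliance, m^3/Pa.
#'   Small but nonzero so prescribed-flow imbalance (scheme C) integrates to
#'   a bounded pressure oscillation.
#' @param r_out Outlet resistance to the constant-pressure sink, Pa s/m^3
#'   (schemes A/B).  Default 1.1e10 (about 8.4 mmHg per ml/min, a
#'   physiological CSF outflow resistance).
#' @param r_prod Production resistance through which the scheme-A inlet
#'   pressure drives flow into the ventricle, Pa s/m^3.
#' @param darcy_leak Enable the trans-parenchymal Darcy pathway between
#'   ventricle and SAS (off by default)?
#' @param leak_path_length,leak_path_area Geometry of the Darcy pathway
#'   (m, m^2), used only when `darcy_leak` is TRUE.
#' @return A list of solver options.
#' @export
solver_options <- function(sas_compliance = 1e-9, r_out = 1.1e10,
                           r_prod = 1e10, darcy_leak = FALSE,
                           leak_path_length = 0.05, leak_path_area = 1e-3) {
  list(sas_compliance = sas_compliance, r_out = r_out, r_prod = r_prod,
       darcy_leak = darcy_leak, leak_path_length = leak_path_length,
       leak_path_area = leak_path_area)
}

# Poiseuille resistance and inertance of the aqueduct duct element
aqueduct_element <- function(radius, length, fluid) {
  list(R = 8 * fluid$viscosity * length / (pi * radius^4),
       L = fluid$density * length / (pi * radius^2))
}

#' Simulate pulsatile CSF flow through the ventricular pathway
#'
#' Backward-Euler integration of a two-node network: the ventricle (volume
#' V, pressure from the viscoelastic cavity model) feeds the subarachnoid
#' space (constant small compliance) through an aqueduct
#' resistance-inertance element; outlets are constant-pressure resistances
#' (schemes A/B) or prescribed flow waveforms (scheme C).  In `"FSI"` mode
#' the ventricular wall is compliant (Prony-series cavity); in `"CFD"` mode
#' it is rigid and the ventricular volume is constant.
#'
#' Each implicit step is one 3x3 linear solve (the network is linear), so
#' mass is conserved to machine precision at every accepted step.  The
#' state starts on the mean-flow operating point, and five cycles are
#' integrated; the last cycle (half-open `[ (n-1)T, nT )`) is the one
#' summarised by the metrics layer.
#'
#' @param subject A [subject_record()] (one-row tibble or list).
#' @param bc A [build_bc()] scheme.
#' @param material A [material_model()].
#' @param mode `"FSI"` (compliant ventricle) or `"CFD"` (rigid).
#' @param dt Time step in s (default 0.01).
#' @param n_cycles Number of cardiac cycles (default 5).
#' @param fluid A [fluid_properties()].
#' @param options A [solver_options()] list.
#' @return A `csf_sim` object: `$series` is a tibble with `time`,
#'   `P_ventricle`, `P_sas`, `Q_in`, `Q_aqueduct`, `Q_out`, `Q_leak`,
#'   `V_ventricle`; plus grid metadata, `cycle_periodicity` (max relative
#'   difference between the last two cycles) and `max_mass_residual`
#'   (relative to peak flow).
#' @export
simulate_csf <- function(subject, bc, material = material_model(),
                         mode = c("FSI", "CFD"), dt = 0.01, n_cycles = 5,
                         fluid = fluid_properties(),
                         options = solver_options()) {
  mode <- match.arg(mode)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(bc, "csf_bc"))
  sub <- as.list(subject)
  period <- bc$period
  n_steps <- round(n_cycles * period / dt)
  times <- seq(0, by = dt, length.out = n_steps + 1L)

  el <- aqueduct_element(sub$aqueduct_radius_m, sub$aqueduct_length_m, fluid)
  R <- el$R; L <- el$L
  v0 <- ml_to_m3(sub$ventricular_volume_ml)
  p0 <- sub$baseline_pressure_pa
  cs <- options$sas_compliance
  kl <- if (isTRUE(options$darcy_leak)) {
    darcy_leak_conductance(material, options$leak_path_length, options$leak_path_area)
  } else 0

  scheme <- bc$scheme
  if (scheme == "C" && cs <= 0) {
    abort("scheme C requires a positive SAS compliance (pressure is undefined at C_S = 0).")
  }

  # prescribed waveform samples on the grid
  qin_t <- if (bc$inlet$type == "flow") wf_eval(bc$inlet$waveform, times) else NULL
  pin_t <- if (bc$inlet$type == "pressure") p0 + bc$inlet$pressure_fun(times) else NULL
  pressure_outlets <- purrr::keep(bc$outlets, ~ .x$type == "pressure")
  flow_outlets <- purrr::keep(bc$outlets, ~ .x$type == "flow")
  qout_t <- if (length(flow_outlets) > 0) {
    Reduce(`+`, purrr::map(flow_outlets, ~ wf_eval(.x$waveform, times)))
  } else rep(0, length(times))
  g_out <- sum(purrr::map_dbl(pressure_outlets, ~ 1 / options$r_out))
  p_sink <- if (length(pressure_outlets) > 0) pressure_outlets[[1]]$pressure else NA_real_

  # viscoelastic cavity coefficients (FSI); see cavity_transmural_pressure
  g0 <- material$shear_modulus
  g <- material$prony_g; tau <- material$prony_tau
  g_inf <- g0 * (1 - sum(g))
  ek <- if (length(g)) exp(-dt / tau) else numeric(0)
  kap <- 4 * g_inf / (3 * v0)
  bet <- if (length(g)) (4 / (3 * v0)) * sum(g0 * g * (tau / dt) * (1 - ek)) else 0

  # mean-flow operating point for consistent initial conditions
  if (scheme == "A" || scheme == "B") {
    q_bar <- if (scheme == "A") 80 / (options$r_prod + R + options$r_out)
             else wf_mean(bc$inlet$waveform)
    ps0 <- p_sink + q_bar / g_out
  } else {
    q_bar <- wf_mean(bc$inlet$waveform)
    ps0 <- p0
  }
  p_ref <- ps0 + R * q_bar   # ventricle node baseline so the mean state is steady

  a_coef <- if (mode == "FSI") kap + bet else 0

  # assemble the constant 3x3 system matrix; unknowns are
  #   FSI: (V, Q, P_S)   with P_V = a_coef * V + c0_n
  #   CFD: (P_V, Q, P_S) with V = v0
  if (mode == "FSI") {
    m11 <- 1 + dt * kl * a_coef + if (scheme == "A") dt * a_coef / options$r_prod else 0
    M <- rbind(
      c(m11, dt, -dt * kl),
      c(-a_coef, L / dt + R, 1),
      c(-kl * a_coef, -1, cs / dt + kl + g_out)
    )
  } else {
    m11 <- -kl - if (scheme == "A") 1 / options$r_prod else 0
    M <- rbind(
      c(m11, -1, kl),
      c(-1, L / dt + R, 1),
      c(-kl, -1, cs / dt + kl + g_out)
    )
  }
  # the raw matrix mixes volumes (~1e-5), flows (~1e-9) and pressures
  # (~1e3): equilibrate rows and columns before inverting, then apply the
  # scaled inverse at every step
  rsc <- 1 / apply(abs(M), 1, max)
  M1 <- M * rsc
  csc <- 1 / apply(abs(M1), 2, max)
  Minv_eq <- solve(sweep(M1, 2, csc, `*`))
  solve_step <- function(b) csc * drop(Minv_eq %*% (rsc * b))

  n_tot <- n_steps + 1L
  P_V <- numeric(n_tot); P_S <- numeric(n_tot); Qa <- numeric(n_tot)
  Qi <- numeric(n_tot); Qo <- numeric(n_tot); Ql <- numeric(n_tot)
  Wv <- numeric(n_tot)   # ventricular volume deviation V - v0 (avoids
                         # catastrophic cancellation in the mass residual)
  h <- numeric(length(g))

  Wv[1] <- 0; Qa[1] <- q_bar; P_S[1] <- ps0; P_V[1] <- p_ref
  Qi[1] <- q_bar
  Qo[1] <- if (g_out > 0) g_out * (ps0 - p_sink) else qout_t[1]
  Ql[1] <- kl * (P_V[1] - P_S[1])

  w_prev <- 0; q_prev <- q_bar; ps_prev <- ps0

  for (k in seq_len(n_steps)) {
    i <- k + 1L
    if (mode == "FSI") {
      # P_V = a_coef * w_new + c0, with w the deviation from v0
      Hn <- if (length(g)) (4 / (3 * v0)) * sum(ek * h) else 0
      c0 <- p_ref - bet * w_prev + Hn
      b1 <- w_prev - dt * kl * c0 +
        if (scheme == "A") dt * (pin_t[i] - c0) / options$r_prod else dt * qin_t[i]
      b2 <- (L / dt) * q_prev + c0
      b3 <- (cs / dt) * ps_prev + kl * c0 - qout_t[i] +
        if (g_out > 0) g_out * p_sink else 0
      x <- solve_step(c(b1, b2, b3))
      w_new <- x[1]; q_new <- x[2]; ps_new <- x[3]
      pv_new <- a_coef * w_new + c0
      if (length(g)) {
        h <- ek * h + g0 * g * ((w_new - w_prev) / dt) * tau * (1 - ek)
      }
    } else {
      b1 <- if (scheme == "A") -pin_t[i] / options$r_prod else -qin_t[i]
      b2 <- (L / dt) * q_prev
      b3 <- (cs / dt) * ps_prev - qout_t[i] +
        if (g_out > 0) g_out * p_sink else 0
      x <- solve_step(c(b1, b2, b3))
      pv_new <- x[1]; q_new <- x[2]; ps_new <- x[3]
      w_new <- 0
    }
    if (!all(is.finite(c(w_new, q_new, ps_new, pv_new)))) {
      abort(sprintf("solver diverged (non-finite state) at step %d (t = %.3f s).",
                    k, times[i]))
    }
    P_V[i] <- pv_new; P_S[i] <- ps_new; Qa[i] <- q_new; Wv[i] <- w_new
    Ql[i] <- kl * (pv_new - ps_new)
    Qi[i] <- if (scheme == "A") (pin_t[i] - pv_new) / options$r_prod else qin_t[i]
    Qo[i] <- if (g_out > 0) g_out * (ps_new - p_sink) else qout_t[i]
    w_prev <- w_new; q_prev <- q_new; ps_prev <- ps_new
  }

  # mass-balance residual of the accepted steps, relative to peak flow
  peak_q <- max(abs(Qa), abs(Qi), 1e-300)
  resid <- if (mode == "FSI") {
    max(abs(diff(Wv) / dt - (Qi[-1] - Qa[-1] - Ql[-1])))
  } else {
    max(abs(Qi[-1] - Qa[-1] - Ql[-1]))
  }

  series <- tibble(time = times, P_ventricle = P_V, P_sas = P_S,
                   Q_in = Qi, Q_aqueduct = Qa, Q_out = Qo, Q_leak = Ql,
                   V_ventricle = v0 + Wv)
  out <- structure(list(
    series = series, dt = dt, period = period, n_cycles = n_cycles,
    mode = mode, scheme = scheme, group = bc$group,
    subject_id = sub$id %||% NA_character_,
    aqueduct_radius_m = sub$aqueduct_radius_m,
    network = list(R = R, L = L, sas_compliance = cs, r_out = options$r_out,
                   r_prod = options$r_prod, leak_conductance = kl,
                   v0 = v0, p_ref = p_ref),
    max_mass_residual = resid / peak_q
  ), class = "csf_sim")
  out$cycle_periodicity <- cycle_periodicity(out)
  out
}

# max relative difference between the last two cycles, across the pressure
# and flow series (normalised by the last cycle's peak magnitude)
cycle_periodicity <- function(sim) {
  if (sim$n_cycles < 2) return(NA_real_)
  s <- sim$series
  idx <- function(cyc) which(s$time >= (cyc - 1) * sim$period - 1e-12 &
                             s$time < cyc * sim$period - 1e-12)
  i4 <- idx(sim$n_cycles - 1); i5 <- idx(sim$n_cycles)
  n <- min(length(i4), length(i5))
  per_series <- purrr::map_dbl(c("P_ventricle", "P_sas", "Q_aqueduct"), function(v) {
    a <- s[[v]][i4[seq_len(n)]]; b <- s[[v]][i5[seq_len(n)]]
    max(abs(a - b)) / max(abs(b), 1e-300)
  })
  max(per_series)
}

#' Extract the reporting cycle of a simulation
#'
#' @param sim A `csf_sim` from [simulate_csf()].
#' @return Tibble of the last cycle's samples, `time` rebased to `[0, T)`.
#' @export
last_cycle <- function(sim) {
  stopifnot(inherits(sim, "csf_sim"))
  t0 <- (sim$n_cycles - 1) * sim$period
  out <- dplyr::filter(sim$series, .data$time >= t0 - 1e-12,
                       .data$time < sim$n_cycles * sim$period - 1e-12)
  dplyr::mutate(out, time = .data$time - t0)
}

#' Run the compliant- and rigid-wall solvers on one subject
#'
#' The pair feeds [compare_runs()]: identical grids, identical boundary
#' conditions, only the ventricular-wall treatment differs.
#'
#' @inheritParams simulate_csf
#' @return List with elements `fsi` and `cfd` (two `csf_sim` objects).
#' @export
run_mode_pair <- function(subject, bc, material = material_model(),
                          dt = 0.01, n_cycles = 5,
                          fluid = fluid_properties(),
                          options = solver_options()) {
  list(
    fsi = simulate_csf(subject, bc, material, mode = "FSI", dt = dt,
                       n_cycles = n_cycles, fluid = fluid, options = options),
    cfd = simulate_csf(subject, bc, material, mode = "CFD", dt = dt,
                       n_cycles = n_cycles, fluid = fluid, options = options)
  )
}

#' Export / import a simulation result as JSON
#'
#' @param sim A `csf_sim` object.
#' @param path Output file.
#' @return `read_simulation_json()` returns the round-tripped `csf_sim`.
#' @export
write_simulation_json <- function(sim, path) {
  stopifnot(inherits(sim, "csf_sim"))
  payload <- list(
    meta = sim[setdiff(names(sim), c("series", "network"))],
    network = sim$network,
    series = as.list(sim$series)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_simulation_json
#' @export
read_simulation_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- c(payload$meta, list(network = payload$network,
                              series = as_tibble(payload$series)))
  structure(out[c("series", setdiff(names(out), "series"))], class = "csf_sim")
}
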