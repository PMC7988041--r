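#' Aqueductal stroke volume from a flow waveform
#'
#' Splits one cycle of the flow-rate diagram into the positive area above
#' the x axis (`A+`, caudal flow) and the negative area below it (`A-`).
#' Two conventions are reported in the field:
#' * `"difference"`: `A+ - A-`, the net volume transported per cycle
#'   (equal to mean flow times period);
#' * `"oscillatory"`: `(A+ + A-)/2`, the volume shuttled back and forth by
#'   the cardiac pulsation — the convention used for aqueductal stroke
#'   volume in clinical work and the default for group comparisons here.
#' Quadrature is trapezoidal with the positive/negative parts split at the
#' linear zero crossings, so it is exact for piecewise-linear samples.
#'
#' @param flow A flow [waveform()] (m^3/s) covering one cycle, or a
#'   `csf_sim` (its last-cycle aqueduct flow is used).
#' @param convention `"oscillatory"` (default) or `"difference"`.
#' @return Stroke volume in ml.
#' @examples
#' t <- seq(0, 0.995, by = 0.005)
#' wf <- waveform(t, 1e-7 * sin(2 * pi * t), units = "m3/s")
#' stroke_volume(wf, "difference")   # ~0: pure oscillation
#' stroke_volume(wf, "oscillatory")  # Q0 * T / pi in ml
#' @export
stroke_volume <- function(flow, convention = c("oscillatory", "difference")) {
  convention <- match.arg(convention)
  if (inherits(flow, "csf_sim")) {
    lc <- last_cycle(flow)
    flow <- waveform(lc$time, lc$Q_aqueduct, period = flow$period, units = "m3/s")
  }
  stopifnot(inherits(flow, "csf_waveform"))
  if (nrow(flow) < 4L) abort("stroke_volume needs at least 4 samples per cycle.")
  period <- wf_period(flow)
  tt <- c(flow$time, period)
  qq <- c(flow$value, flow$value[1])
  pos <- 0; neg <- 0
  for (i in seq_len(length(tt) - 1L)) {
    t1 <- tt[i]; t2 <- tt[i + 1L]; q1 <- qq[i]; q2 <- qq[i + 1L]
    if (q1 >= 0 && q2 >= 0) {
      pos <- pos + (t2 - t1) * (q1 + q2) / 2
    } else if (q1 <= 0 && q2 <= 0) {
      neg <- neg - (t2 - t1) * (q1 + q2) / 2
    } else {
      tc <- t1 + (t2 - t1) * q1 / (q1 - q2)  # linear zero crossing
      a1 <- (tc - t1) * q1 / 2
      a2 <- (t2 - tc) * q2 / 2
      pos <- pos + max(a1, 0) + max(a2, 0)
      neg <- neg - min(a1, 0) - min(a2, 0)
    }
  }
  vol_m3 <- if (convention == "difference") pos - neg else (pos + neg) / 2
  m3_to_ml(vol_m3)
}

#' Reynolds number of the aqueduct flow
#'
#' `Re = rho u D / mu` with `D` the aqueduct diameter; values below ~2000
#' indicate laminar flow.
#'
#' @param u_max Peak axial velocity, m/s (>= 0).
#' @param diameter Aqueduct diameter, m (> 0).
#' @param fluid A [fluid_properties()].
#' @return Dimensionless Reynolds number.
#' @export
reynolds <- function(u_max, diameter, fluid = fluid_properties()) {
  check_number(u_max, "u_max", lower = 0)
  check_number(diameter, "diameter", lower = 0, strict_lower = TRUE)
  fluid$density * u_max * diameter / fluid$viscosity
}

#' Peak (or trough) value and its phase in the cardiac cycle
#'
#' @param series A [waveform()], or a `csf_sim` with `node` naming a series
#'   column of its last cycle.
#' @param which `"max"` or `"min"`.
#' @param node Series name when `series` is a simulation (default
#'   `"P_sas"`).
#' @return Tibble with `value` and `phase` (fraction of the cycle in
#'   `[0, 1)`); ties are broken at the earliest phase.
#' @export
peak_phase <- function(series, which = c("max", "min"), node = "P_sas") {
  which <- match.arg(which)
  if (inherits(series, "csf_sim")) {
    lc <- last_cycle(series)
    series <- waveform(lc$time, lc[[node]], period = series$period)
  }
  stopifnot(inherits(series, "csf_waveform"))
  if (nrow(series) == 0) abort("peak_phase needs a non-empty series.")
  idx <- if (which == "max") which.max(series$value) else which.min(series$value)
  tibble(value = series$value[idx],
         phase = series$time[idx] / wf_period(series))
}

#' Compare two simulations at one node
#'
#' Used for the rigid-wall (CFD) versus compliant-wall (FSI) comparison:
#' the relative difference of the last-cycle peak values at a node, and the
#' phase difference of the peaks as a percentage of the cycle.
#'
#' @param a,b Two `csf_sim` objects on identical grids.
#' @param node Series column to compare (default `"P_sas"`).
#' @return Tibble with `max_rel_diff_percent` and `phase_diff_percent`.
#' @export
compare_runs <- function(a, b, node = "P_sas") {
  stopifnot(inherits(a, "csf_sim"), inherits(b, "csf_sim"))
  if (a$dt != b$dt || a$n_cycles != b$n_cycles || a$period != b$period) {
    abort("compare_runs requires identical time grids.")
  }
  pa <- peak_phase(a, "max", node = node)
  pb <- peak_phase(b, "max", node = node)
  dphase <- abs(pa$phase - pb$phase)
  dphase <- min(dphase, 1 - dphase)  # wrap on the cycle
  tibble(
    max_rel_diff_percent = 100 * abs(pa$value - pb$value) / abs(pa$value),
    phase_diff_percent = 100 * dphase
  )
}

#' Hydrodynamic summary of one simulation
#'
#' One row of the metrics the boundary-condition comparison is built on:
#' both stroke-volume conventions, the peak Reynolds number and laminarity
#' flag, and the peak/trough pressures and peak velocity with their phases.
#'
#' @param sim A `csf_sim`.
#' @param fluid A [fluid_properties()].
#' @param node Pressure node summarised for peaks (default `"P_sas"`).
#' @param velocity_method Profile used by [peak_aqueduct_velocity()].
#' @return One-row tibble of class `csf_metrics`.
#' @export
hydro_metrics <- function(sim, fluid = fluid_properties(), node = "P_sas",
                          velocity_method = "poiseuille") {
  stopifnot(inherits(sim, "csf_sim"))
  lc <- last_cycle(sim)
  qwf <- waveform(lc$time, lc$Q_aqueduct, period = sim$period, units = "m3/s")
  u_max <- peak_aqueduct_velocity(sim, fluid = fluid, method = velocity_method)
  re <- reynolds(u_max, 2 * sim$aqueduct_radius_m, fluid)
  pk <- peak_phase(sim, "max", node = node)
  tr <- peak_phase(sim, "min", node = node)
  uwf <- waveform(lc$time, abs(lc$Q_aqueduct), period = sim$period)
  upk <- peak_phase(uwf, "max")
  out <- tibble(
    subject_id = sim$subject_id, group = sim$group, scheme = sim$scheme,
    mode = sim$mode,
    stroke_volume_oscillatory_ml = stroke_volume(qwf, "oscillatory"),
    stroke_volume_difference_ml = stroke_volume(qwf, "difference"),
    peak_velocity_m_s = u_max,
    peak_velocity_phase = upk$phase,
    reynolds_max = re,
    laminar = re < 2000,
    peak_pressure_pa = pk$value, peak_pressure_phase = pk$phase,
    min_pressure_pa = tr$value, min_pressure_phase = tr$phase,
    cycle_periodicity = sim$cycle_periodicity
  )
  class(out) <- c("csf_metrics", class(out))
  out
}
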