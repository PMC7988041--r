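#' Specification for a synthetic cohort
#'
#' Defines the study conditions the generator emulates: two groups whose
#' compartment-volume distributions match the cohort tables' means and SDs,
#' baseline pressures at the group outlet levels (500 / 2700 Pa), cardiac
#' waveforms peaking at 17.5% of the cycle, and group oscillatory
#' aqueductal stroke-volume targets in the ratio ~7.9 (healthy 0.04 ml, a
#' physiological value; patients 0.316 ml).
#'
#' @param n_healthy,n_patients Group sizes (defaults 8 and 11, the study
#'   cohort sizes).
#' @param volumes Per-group (mean, sd) in ml for each compartment.
#' @param stroke_targets_ml Oscillatory aqueductal stroke-volume target per
#'   group, ml per cycle.
#' @param radius Per-group (mean, sd) of aqueduct radius, m (patients
#'   wider, reflecting ventriculomegaly; the radii are conventions, truncated
#'   to 0.5-3 mm).
#' @param baseline_pressure_pa Per-group baseline pressure, Pa.
#' @param n_harmonics,harmonic_decay,harmonic_jitter Waveform morphology
#'   parameters (see [generate_waveform()]).
#' @param phase_of_peak Cycle fraction where the systolic flow peak sits
#'   (default 0.175).
#' @param period Cardiac period, s.
#' @param seed Mandatory integer seed.
#' @return A `csf_cohort_spec` list.
#' @export
cohort_spec <- function(n_healthy = 8, n_patients = 11,
                        volumes = list(
                          healthy = list(ventricular = c(20.3, 0.8),
                                         brain = c(1297.0, 52.1),
                                         sas = c(105.9, 4.8)),
                          patient = list(ventricular = c(281.6, 11.5),
                                         brain = c(1071.7, 48.6),
                                         sas = c(108.4, 4.7))),
                        stroke_targets_ml = c(healthy = 0.04, patient = 0.316),
                        radius = list(healthy = c(1.0e-3, 0.1e-3),
                                      patient = c(1.5e-3, 0.15e-3)),
                        baseline_pressure_pa = c(healthy = 500, patient = 2700),
                        n_harmonics = 4, harmonic_decay = 0.5,
                        harmonic_jitter = 0.15,
                        phase_of_peak = 0.175, period = 1, seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory for cohort generation (no silent clock seeds).")
  }
  for (grp in c("healthy", "patient")) {
    for (v in names(volumes[[grp]])) {
      if (any(volumes[[grp]][[v]] < 0)) abort("volume means/sds must be >= 0.")
    }
  }
  if (any(stroke_targets_ml <= 0)) abort("stroke-volume targets must be positive.")
  check_number(phase_of_peak, "phase_of_peak", lower = 0, upper = 1,
               strict_upper = TRUE)
  structure(list(
    n_healthy = n_healthy, n_patients = n_patients, volumes = volumes,
    stroke_targets_ml = stroke_targets_ml, radius = radius,
    baseline_pressure_pa = baseline_pressure_pa, n_harmonics = n_harmonics,
    harmonic_decay = harmonic_decay, harmonic_jitter = harmonic_jitter,
    phase_of_peak = phase_of_peak, period = period, seed = as.integer(seed)
  ), class = "csf_cohort_spec")
}

# truncated normal by redraw at +/- 3 sd (the summaries are symmetric and
# pass normality testing, so a light truncation only guards the tails)
rtruncnorm3 <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  x <- rnorm(n, mean, sd)
  bad <- abs(x - mean) > 3 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > 3 * sd
  }
  x
}

#' Generate a normalized cardiac flow shape
#'
#' A truncated Fourier series of aligned cosine harmonics with geometrically
#' decaying, randomly perturbed coefficients.  All harmonics peak together
#' at `phase_of_peak`, so the waveform has zero cycle mean by construction,
#' unit peak value (+1) exactly at the requested phase, and a realistic
#' sharp-systole/flat-diastole morphology.
#'
#' @param n_harmonics Number of harmonics (>= 1).
#' @param phase_of_peak Peak location as a cycle fraction in `[0, 1)`.
#' @param seed Integer seed (mandatory).
#' @param decay Geometric decay of harmonic amplitudes.
#' @param jitter Relative uniform perturbation of each amplitude.
#' @param n_samples Samples per cycle (default 200, so the default peak
#'   phase 0.175 lies on the grid).
#' @param period Cycle length, s.
#' @return A normalized `csf_waveform`.
#' @export
generate_waveform <- function(n_harmonics = 4, phase_of_peak = 0.175, seed,
                              decay = 0.5, jitter = 0.15, n_samples = 200,
                              period = 1) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  if (n_harmonics < 1) abort("need at least one harmonic.")
  check_number(phase_of_peak, "phase_of_peak", lower = 0, upper = 1,
               strict_upper = TRUE)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  coef <- withr_seed(
    decay^(seq_len(n_harmonics) - 1) *
      (1 + jitter * runif(n_harmonics, -1, 1))
  )
  phi <- seq(0, 1 - 1 / n_samples, length.out = n_samples)
  s <- rep(0, n_samples)
  for (m in seq_len(n_harmonics)) {
    s <- s + coef[m] * cos(2 * pi * m * (phi - phase_of_peak))
  }
  s <- s / sum(coef)  # aligned positive harmonics: peak value is sum(coef)
  waveform(phi * period, s, period = period, units = "normalized")
}

#' Generate a synthetic cohort of subjects
#'
#' Draws compartment volumes from truncated normal distributions at the
#' specified group (mean, sd), builds per-subject cardiac waveforms, and
#' (by default) calibrates each subject's pulsatile inlet amplitude so the
#' solver's oscillatory aqueductal stroke volume under scheme C hits the
#' group target — which fixes the patient/healthy stroke-volume ratio near
#' 7.9 by construction.  Fully reproducible given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param calibrate Calibrate amplitudes through the solver (default TRUE)?
#'   When FALSE a shared analytic initial guess is used instead (volumes
#'   and waveforms are unaffected).
#' @return Tibble of subjects (class `csf_synthetic_cohort`) with a
#'   `waveform` list-column and `amplitude_m3s`.
#' @export
generate_cohort <- function(spec, calibrate = TRUE) {
  stopifnot(inherits(spec, "csf_cohort_spec"))
  set.seed(spec$seed)
  groups <- c(rep("healthy", spec$n_healthy), rep("patient", spec$n_patients))
  if (length(groups) == 0) return(empty_cohort())
  rows <- purrr::map_dfr(seq_along(groups), function(i) {
    grp <- groups[i]
    vols <- spec$volumes[[grp]]
    rad <- rtruncnorm3(1, spec$radius[[grp]][1], spec$radius[[grp]][2])
    rad <- min(max(rad, 0.5e-3), 3e-3)
    tibble(
      id = sprintf("%s_%02d", if (grp == "healthy") "H" else "P",
                   sum(groups[seq_len(i)] == grp)),
      group = grp,
      ventricular_volume_ml = rtruncnorm3(1, vols$ventricular[1], vols$ventricular[2]),
      brain_volume_ml = rtruncnorm3(1, vols$brain[1], vols$brain[2]),
      sas_volume_ml = rtruncnorm3(1, vols$sas[1], vols$sas[2]),
      aqueduct_radius_m = rad,
      aqueduct_length_m = 15e-3,
      baseline_pressure_pa = spec$baseline_pressure_pa[[grp]],
      waveform_seed = sample.int(.Machine$integer.max, 1),
      measured_icp_pa = NA_real_
    )
  })
  rows$waveform <- purrr::map(rows$waveform_seed, function(s) {
    generate_waveform(spec$n_harmonics, spec$phase_of_peak, seed = s,
                      decay = spec$harmonic_decay, jitter = spec$harmonic_jitter,
                      period = spec$period)
  })
  rows$stroke_target_ml <- spec$stroke_targets_ml[rows$group]
  rows$amplitude_m3s <- purrr::map_dbl(seq_len(nrow(rows)), function(i) {
    target <- rows$stroke_target_ml[i]
    guess <- ml_to_m3(target) * pi / spec$period  # sinusoid-equivalent
    if (!calibrate) return(guess)
    calibrate_amplitude(rows[i, ], target, guess, spec)
  })
  class(rows) <- c("csf_synthetic_cohort", class(rows))
  rows
}

empty_cohort <- function() {
  out <- tibble(id = character(), group = character(),
                ventricular_volume_ml = numeric(), brain_volume_ml = numeric(),
                sas_volume_ml = numeric(), aqueduct_radius_m = numeric(),
                aqueduct_length_m = numeric(), baseline_pressure_pa = numeric(),
                waveform_seed = integer(), measured_icp_pa = numeric(),
                waveform = list(), stroke_target_ml = numeric(),
                amplitude_m3s = numeric())
  class(out) <- c("csf_synthetic_cohort", class(out))
  out
}

# secant iteration on the (nearly linear) amplitude -> oscillatory
# stroke-volume map; short runs (3 cycles) are enough because the solver
# starts on the periodic operating point
calibrate_amplitude <- function(subject, target_ml, guess, spec,
                                tol = 0.01, max_iter = 4) {
  sv_at <- function(amp) {
    bc <- build_bc("C", subject$group, shape = subject$waveform[[1]],
                   amplitude = amp, period = spec$period)
    sim <- simulate_csf(subject, bc, mode = "FSI", n_cycles = 3)
    stroke_volume(sim, "oscillatory")
  }
  a1 <- guess
  s1 <- sv_at(a1)
  for (iter in seq_len(max_iter)) {
    if (abs(s1 - target_ml) <= tol * target_ml) break
    a2 <- a1 * target_ml / s1
    s2 <- sv_at(a2)
    # secant update using the two evaluations
    if (abs(s2 - s1) > 1e-15) {
      a_next <- a1 + (target_ml - s1) * (a2 - a1) / (s2 - s1)
      if (a_next > 0) {
        a1 <- a_next; s1 <- sv_at(a1)
        next
      }
    }
    a1 <- a2; s1 <- s2
  }
  a1
}

#' Convert a synthetic cohort to the cohort-table schema
#'
#' Produces tables in the same long schema as the bundled fixtures, so the
#' statistics layer runs unchanged on synthetic data.  Simulated pressure
#' maxima can be appended by passing metric rows from [hydro_metrics()].
#'
#' @param cohort A [generate_cohort()] result.
#' @param metrics Optional `csf_metrics` rows (one per subject x scheme)
#'   whose peak SAS/CA pressures are added as `max_pressure_*` variables.
#' @return Named list of `csf_cohort` tibbles, one per group present.
#' @export
cohort_to_tables <- function(cohort, metrics = NULL) {
  if (nrow(cohort) == 0) abort("cannot tabulate an empty cohort.")
  base <- cohort |>
    dplyr::select("id", "group", "ventricular_volume_ml", "brain_volume_ml",
                  "sas_volume_ml") |>
    tidyr::pivot_longer(cols = dplyr::ends_with("_ml"), names_to = "variable",
                        values_to = "value") |>
    dplyr::transmute(.data$group, subject = .data$id,
                     variable = sub("_ml$", "", .data$variable),
                     unit = "ml", .data$value)
  if (!is.null(metrics)) {
    extra <- metrics |>
      dplyr::transmute(group = .data$group, subject = .data$subject_id,
                       variable = paste0("max_pressure_SAS_BC_", .data$scheme),
                       unit = "Pa", value = .data$peak_pressure_pa)
    base <- dplyr::bind_rows(base, extra)
  }
  split(base, base$group) |>
    purrr::map(new_cohort_table)
}
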