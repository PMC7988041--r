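#' Scheme-A sinusoidal inlet pressure
#'
#' Scheme A drives the inlet with the sinusoidal pressure
#' 80 + 160 sin(2 pi t / period) Pa, a perturbation superposed on the
#' group's baseline pressure when the network is assembled.
#'
#' @param t Time in s (vectorised).
#' @param period Cardiac period in s (default 1).
#' @return Pressure in Pa.
#' @examples
#' bc_a_inlet_pressure(c(0, 0.25, 0.75))  # 80, 240, -80
#' @export
bc_a_inlet_pressure <- function(t, period = 1) {
  80 + 160 * sin(2 * pi * t / period)
}

#' Constant outlet (sagittal-sinus baseline) pressure by group
#'
#' @param group `"healthy"` (500 Pa) or `"patient"` (2700 Pa).
#' @return Pressure in Pa.
#' @export
outlet_pressure <- function(group) {
  if (!is.character(group) || length(group) != 1L ||
      !group %in% c("healthy", "patient")) {
    abort("`group` must be \"healthy\" or \"patient\".")
  }
  c(healthy = 500, patient = 2700)[[group]]
}

#' Superpose a mean flow and a pulsatile shape into a flow waveform
#'
#' Builds `Q(t) = mean_flow + amplitude * shape(t)` from a normalized
#' pulsatile shape.  The shape is renormalized to zero cycle mean and unit
#' peak (its maximum value becomes exactly +1) before scaling, so the cycle
#' mean of the result equals `mean_flow` to quadrature accuracy.
#'
#' @param shape A [waveform()] giving the normalized pulsatile morphology.
#' @param mean_flow Cycle-mean flow in m^3/s.
#' @param amplitude Pulsatile amplitude in m^3/s (peak of the oscillatory
#'   component above the mean).
#' @return A flow `csf_waveform` in m^3/s.
#' @export
superpose_flow <- function(shape, mean_flow, amplitude) {
  stopifnot(inherits(shape, "csf_waveform"))
  if (nrow(shape) < 2L) abort("pulsatile shape must have at least 2 samples.")
  s <- shape$value - wf_mean(shape)
  peak <- max(s)
  if (peak > 0) s <- s / peak
  waveform(shape$time, mean_flow + amplitude * s,
           period = wf_period(shape), units = "m3/s")
}

#' Assemble one of the three inlet/outlet boundary-condition schemes
#'
#' * Scheme `"A"`: sinusoidal inlet pressure [bc_a_inlet_pressure()] and a
#'   single constant-pressure outlet at the group baseline
#'   ([outlet_pressure()]).
#' * Scheme `"B"`: pulsatile inlet flow with cycle mean 0.35 ml/min
#'   (production rate), same constant-pressure outlet as scheme A.
#' * Scheme `"C"`: the same pulsatile inlet flow as scheme B, and two
#'   pulsatile outlet flows (sagittal sinus and spinal canal) that reuse
#'   the inlet morphology scaled to means 0.18 and 0.17 ml/min, so mean
#'   mass balance holds exactly by construction.
#'
#' @param scheme `"A"`, `"B"` or `"C"`.
#' @param group `"healthy"` or `"patient"`.
#' @param shape Normalized pulsatile shape [waveform()] used by schemes
#'   B/C (defaults to a single-harmonic shape); ignored by scheme A.
#' @param amplitude Pulsatile inlet amplitude in m^3/s for schemes B/C.
#' @param mean_inflow_ml_min Cycle-mean production rate, ml/min.
#' @param outlet_means_ml_min Means of the two scheme-C outlets, ml/min;
#'   must sum to `mean_inflow_ml_min`.
#' @param period Cardiac period in s.
#' @return A `csf_bc` list with fields `scheme`, `group`, `period`,
#'   `inlet` and `outlets`.
#' @export
build_bc <- function(scheme = c("A", "B", "C"),
                     group = c("healthy", "patient"),
                     shape = NULL,
                     amplitude = 1e-7,
                     mean_inflow_ml_min = 0.35,
                     outlet_means_ml_min = c(0.18, 0.17),
                     period = 1) {
  scheme <- match.arg(scheme)
  group <- match.arg(group)
  p_out <- outlet_pressure(group)
  if (is.null(shape)) {
    tt <- seq(0, period - period / 200, length.out = 200)
    shape <- waveform(tt, sin(2 * pi * tt / period), period = period)
  }
  mean_in <- ml_min_to_m3s(mean_inflow_ml_min)

  if (scheme == "A") {
    inlet <- list(type = "pressure",
                  pressure_fun = function(t) bc_a_inlet_pressure(t, period))
    outlets <- list(list(location = "sagittal_sinus", type = "pressure",
                         pressure = p_out))
  } else {
    inlet_wf <- superpose_flow(shape, mean_in, amplitude)
    inlet <- list(type = "flow", waveform = inlet_wf)
    if (scheme == "B") {
      outlets <- list(list(location = "sagittal_sinus", type = "pressure",
                           pressure = p_out))
    } else {
      if (length(outlet_means_ml_min) != 2L) {
        abort("scheme C needs exactly two outlet means (sagittal sinus, spinal canal).")
      }
      if (abs(sum(outlet_means_ml_min) - mean_inflow_ml_min) >
          1e-9 * mean_inflow_ml_min) {
        abort(sprintf(
          "scheme C violates mean mass balance: outlet means sum to %g but inlet mean is %g ml/min.",
          sum(outlet_means_ml_min), mean_inflow_ml_min))
      }
      # outlets reuse the inlet morphology, scaled proportionally to their
      # means: identical phase, exact analytic mean mass balance
      frac <- outlet_means_ml_min / mean_inflow_ml_min
      locs <- c("sagittal_sinus", "spinal_canal")
      outlets <- purrr::map2(frac, locs, function(f, loc) {
        list(location = loc, type = "flow",
             waveform = waveform(inlet_wf$time, f * inlet_wf$value,
                                 period = period, units = "m3/s"))
      })
    }
  }
  structure(list(scheme = scheme, group = group, period = period,
                 inlet = inlet, outlets = outlets,
                 baseline_outlet_pressure = p_out),
            class = "csf_bc")
}
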