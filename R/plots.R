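# ggplot2 views of the package's result objects

#' Plot a simulation's pressure and flow series
#'
#' @param object A `csf_sim`.
#' @param last_cycle_only Show only the reporting cycle (default TRUE)?
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.csf_sim <- function(object, last_cycle_only = TRUE, ...) {
  dat <- tidy(object, last_cycle_only = last_cycle_only)
  dat <- dplyr::filter(dat, .data$series %in%
                         c("P_ventricle", "P_sas", "Q_aqueduct", "Q_in"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(
      x = "time (s)", y = NULL,
      title = sprintf("Scheme %s, %s mode (%s)", object$scheme, object$mode,
                      object$group),
      subtitle = "pressures in Pa, flows in m³/s"
    )
}

#' Plot a waveform
#'
#' @param object A `csf_waveform`.
#' @param ... Unused.
#' @export
autoplot.csf_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = wf_units(object))
}

#' Plot recomputed versus printed claim values
#'
#' @param object A `csf_claims` report.
#' @param ... Unused.
#' @export
autoplot.csf_claims <- function(object, ...) {
  dat <- tidyr::pivot_longer(object, cols = c("recomputed", "printed"),
                             names_to = "source", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(.data$value, .data$claim,
                                    shape = .data$source,
                                    colour = .data$category)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "value", y = NULL,
                  title = "Recomputed vs printed cohort claims")
}
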