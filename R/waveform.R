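#' Periodic waveform objects
#'
#' A waveform is one cardiac cycle of a sampled periodic signal: a tibble
#' with columns `time` (s) and `value`, plus attributes `period` (s) and
#' `units`.  Samples must start at time 0, be strictly increasing, and stop
#' before the period; evaluation wraps periodically with linear
#' interpolation.  Internally flows are in m^3/s and pressures in Pa;
#' `ml/min` values are converted on read/write only.
#'
#' @param time Sample times in seconds, strictly increasing, starting at 0,
#'   all less than `period`.
#' @param value Sample values (finite).
#' @param period Cycle length in seconds (default 1, one cardiac cycle).
#' @param units Unit string for `value` (e.g. `"Pa"`, `"m3/s"`).
#' @return A `csf_waveform` tibble.
#' @examples
#' t <- seq(0, 0.99, by = 0.01)
#' wf <- waveform(t, sin(2 * pi * t), units = "m3/s")
#' wf_eval(wf, c(0.25, 1.25))  # periodic wrap
#' @export
waveform <- function(time, value, period = 1, units = "unitless") {
  check_number(period, "period", lower = 0, strict_lower = TRUE)
  if (length(time) != length(value) || length(time) < 2L) {
    abort("`time` and `value` must have equal length >= 2.")
  }
  if (!all(is.finite(time)) || !all(is.finite(value))) {
    abort("waveform samples must be finite.")
  }
  if (time[1] != 0) abort("waveform must start at time 0.")
  d <- diff(time)
  if (any(d <= 0)) {
    abort(sprintf("waveform times must be strictly increasing (violated at row %d).",
                  which(d <= 0)[1] + 1L))
  }
  if (time[length(time)] >= period) {
    abort("waveform times must stay below the period (one open cycle).")
  }
  out <- tibble(time = as.numeric(time), value = as.numeric(value))
  attr(out, "period") <- period
  attr(out, "units") <- units
  class(out) <- c("csf_waveform", class(out))
  out
}

wf_period <- function(wf) attr(wf, "period")
wf_units <- function(wf) attr(wf, "units")

#' Evaluate a waveform at arbitrary times
#'
#' Linear interpolation on the sampled cycle, wrapped periodically, so
#' `wf_eval(wf, t)` and `wf_eval(wf, t + period)` agree exactly.
#'
#' @param wf A [waveform()].
#' @param t Times (s) at which to evaluate.
#' @return Numeric vector of values.
#' @export
wf_eval <- function(wf, t) {
  period <- wf_period(wf)
  phase <- t %% period
  # close the cycle for interpolation: value at `period` equals value at 0
  xt <- c(wf$time, period)
  xv <- c(wf$value, wf$value[1])
  approx(xt, xv, xout = phase, method = "linear", ties = "ordered")$y
}

#' Cycle mean of a waveform (trapezoidal, with periodic closure)
#'
#' @param wf A [waveform()].
#' @return Mean value over one period.
#' @export
wf_mean <- function(wf) {
  period <- wf_period(wf)
  xt <- c(wf$time, period)
  xv <- c(wf$value, wf$value[1])
  sum(diff(xt) * (utils::head(xv, -1) + utils::tail(xv, -1)) / 2) / period
}

#' Read / write a waveform CSV
#'
#' The file stores one cycle as `time_s,value` rows, preceded by comment
#' headers `# period_s: <p>` and `# units: <u>`.  Values declared in
#' `ml/min` are converted to m^3/s on read (and back on write), so that all
#' in-memory flows are SI.
#'
#' @param path File path.
#' @return [read_waveform()] returns a `csf_waveform`; [write_waveform()]
#'   returns `path` invisibly.
#' @export
read_waveform <- function(path) {
  if (!file.exists(path)) abort(sprintf("waveform file '%s' does not exist.", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(m) == 0) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", m[1]))
  }
  period <- as.numeric(get_field("period_s", "1"))
  units <- get_field("units", "unitless")
  body <- lines[!grepl("^#", lines)]
  dat <- readr::read_csv(I(paste(body, collapse = "\n")),
                         col_types = readr::cols(.default = readr::col_double()))
  if (!all(c("time_s", "value") %in% names(dat))) {
    abort("waveform CSV must have columns time_s,value.")
  }
  d <- diff(dat$time_s)
  if (any(d <= 0)) {
    abort(sprintf("non-monotone time column in '%s' at row %d.",
                  path, which(d <= 0)[1] + 1L))
  }
  value <- dat$value
  if (identical(units, "ml/min")) {
    value <- ml_min_to_m3s(value)
    units <- "m3/s"
  }
  waveform(dat$time_s, value, period = period, units = units)
}

#' @param wf A [waveform()] to write.
#' @rdname read_waveform
#' @export
write_waveform <- function(wf, path) {
  stopifnot(inherits(wf, "csf_waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# period_s: %.17g", wf_period(wf)), con)
  writeLines(sprintf("# units: %s", wf_units(wf)), con)
  writeLines("time_s,value", con)
  writeLines(sprintf("%.17g,%.17g", wf$time, wf$value), con)
  invisible(path)
}
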