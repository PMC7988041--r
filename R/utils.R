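# Unit conversions and small numeric helpers shared across modules.
# Internal computation is SI throughout (Pa, m^3, m^3/s, s, m); millilitres
# and ml/min appear only at I/O boundaries.

ML_PER_M3 <- 1e6
M3S_PER_ML_MIN <- 1 / 6e7

ml_to_m3 <- function(x) x / ML_PER_M3
m3_to_ml <- function(x) x * ML_PER_M3
ml_min_to_m3s <- function(x) x * M3S_PER_ML_MIN
m3s_to_ml_min <- function(x) x / M3S_PER_ML_MIN

#' Round half away from zero at a fixed number of decimals
#'
#' Decimal rounding with ties going up in magnitude (0.5 -> 1), the
#' convention used when comparing recomputed cohort quantities against
#' values printed at fixed precision.  Base [round()] rounds ties to even,
#' which disagrees exactly at the half-digit boundaries that matter here.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(0.25, 1)  # 0.3, where round(0.25, 1) gives 0.2
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stopifnot-style scalar checks with readable errors
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    abort(sprintf(
      "`%s` = %g is outside the admissible range %s%g, %g%s.",
      name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}

# Bessel functions J0, J1 for complex argument, by power series.  Base R's
# besselJ is real-only and no installed package evaluates Bessel functions of
# complex argument; the oscillatory duct profile needs J at arguments along
# exp(3i*pi/4).  The series is accurate to ~1e-8 relative for |z| <= 20,
# which covers Womersley numbers up to ~14; larger arguments are rejected.
besselJ_complex <- function(z, nu) {
  stopifnot(nu %in% c(0L, 1L))
  if (any(Mod(z) > 20)) {
    abort("complex Bessel series is only supported for |z| <= 20.")
  }
  z <- as.complex(z)
  q <- -(z * z) / 4
  term <- if (nu == 0L) rep(1 + 0i, length(z)) else z / 2
  total <- term
  for (m in seq_len(60L)) {
    term <- term * q / (m * (m + nu))
    total <- total + term
    if (all(Mod(term) < 1e-17 * pmax(Mod(total), 1e-300))) break
  }
  total
}

# file digest used by run manifests (no external digest package required)
file_digest <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", n = file.info(path)$size)
  # FNV-1a 64-bit over the file bytes, reported as hex
  h <- 0
  prime <- 1099511628211
  mod <- 2^53  # stay within exact double integer range
  for (b in as.integer(bytes)) {
    h <- bitwXor(h %% 2^31, b) + (h %/% 2^31) * 2^31  # xor on low 31 bits
    h <- (h * (prime %% 2^20) + h %% 97) %% mod
  }
  sprintf("%013.0f", h)
}

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "csfbc")
  if (identical(path, "")) {
    abort(sprintf("bundled data file '%s' is missing from the installation.", file))
  }
  path
}
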