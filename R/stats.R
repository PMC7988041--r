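#' Descriptive statistics of one measurement vector
#'
#' The summary used throughout the cohort tables: sample mean, SD (n-1
#' denominator), standard error, coefficient of variation (100 SD/mean) and
#' the Student-t 95% confidence interval `mean +/- t(0.975, n-1) SE`.
#' Missing values (e.g. the unmeasured patient-11 ICP) are dropped first,
#' so comparisons against the measured subset use the correct n.
#'
#' @param values Numeric vector, at least two non-missing values.
#' @return One-row tibble: `n`, `mean`, `sd`, `se`, `cv_percent`,
#'   `ci_lower`, `ci_upper`.
#' @examples
#' describe_values(c(0, 2))  # ci half-width = t(0.975, 1) = 12.706
#' @export
describe_values <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 2L) abort("descriptive statistics need at least 2 non-missing values.")
  if (!all(is.finite(x))) abort("values must be finite.")
  m <- mean(x)
  if (m == 0) abort("coefficient of variation is undefined for zero mean.")
  s <- sd(x)
  se <- s / sqrt(n)
  half <- qt(0.975, n - 1) * se
  tibble(n = n, mean = m, sd = s, se = se, cv_percent = 100 * s / m,
         ci_lower = m - half, ci_upper = m + half)
}

#' Descriptive statistics of every variable in a cohort table
#'
#' @param cohort A `csf_cohort` tibble ([load_cohort_fixture()] or
#'   [cohort_to_tables()] output).
#' @return Tibble with one row per variable (unit carried along).
#' @export
cohort_descriptives <- function(cohort) {
  stopifnot(inherits(cohort, "csf_cohort"))
  # single-subject groups are summarised by their value alone (dispersion
  # statistics are undefined and reported as NA)
  describe_or_na <- function(values) {
    x <- values[!is.na(values)]
    if (length(x) >= 2L && mean(x) != 0) return(describe_values(values))
    tibble(n = length(x), mean = if (length(x)) mean(x) else NA_real_,
           sd = NA_real_, se = NA_real_, cv_percent = NA_real_,
           ci_lower = NA_real_, ci_upper = NA_real_)
  }
  cohort |>
    dplyr::group_by(.data$group, .data$variable, .data$unit) |>
    dplyr::reframe(describe_or_na(.data$value)) |>
    dplyr::ungroup()
}

#' Pearson correlation with t-based two-sided p value
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both with nonzero
#'   variance.  Pairs with a missing member are dropped.
#' @return Tibble with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) abort("Pearson correlation needs n >= 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("Pearson correlation is undefined for zero variance.")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Shapiro-Wilk normality test
#'
#' Normality gate used before the parametric comparisons; supported for
#' 3 <= n <= 50 (the cohort sizes here are 8 and 11).
#'
#' @param values Numeric vector.
#' @return Tibble with `W` and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3L || length(x) > 50L) {
    abort("Shapiro-Wilk test supported for 3 <= n <= 50.")
  }
  sw <- shapiro.test(x)
  tibble(W = unname(sw$statistic), p_value = sw$p.value)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' @param data Data frame with a numeric `value` column and a `group`
#'   column, or a named list of numeric vectors.
#' @return List with `F`, `p_value`, `df`, and `tukey` (tibble of pairwise
#'   differences with adjusted p values from the studentized range).
#' @export
anova_tukey <- function(data) {
  if (is.list(data) && !is.data.frame(data)) {
    nm <- names(data) %||% paste0("g", seq_along(data))
    data <- purrr::map2_dfr(data, nm, ~ tibble(value = .x, group = .y))
  }
  stopifnot(all(c("value", "group") %in% names(data)))
  if (dplyr::n_distinct(data$group) < 2L) abort("ANOVA needs at least 2 groups.")
  sizes <- dplyr::count(data, .data$group)
  if (any(sizes$n < 2L)) abort("every group needs at least 2 observations.")
  data$group <- factor(data$group)
  fit <- aov(value ~ group, data = data)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  tukey <- tibble(
    pair = rownames(tk), diff = tk[, "diff"],
    ci_lower = tk[, "lwr"], ci_upper = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  list(F = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
       df = unname(an[["Df"]]), tukey = tukey)
}

#' Pooled-variance two-sample t test with a variance-equality gate
#'
#' Student's t test assuming equal variances, reported together with the
#' p value of the preliminary F test of variance equality (reported as a
#' gate; no automatic switch to the unequal-variance form).
#'
#' @param x,y Numeric vectors (n >= 2 each; missing values dropped).
#' @return Tibble with `t`, `p_value`, `df`, `variance_equality_p`.
#' @export
t_test_pooled <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) abort("t test needs n >= 2 per sample.")
  tt <- t.test(x, y, var.equal = TRUE)
  vt <- var.test(x, y)
  tibble(t = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter), variance_equality_p = vt$p.value)
}
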