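test_that("describe_values matches hand-computed summary statistics", {
  x <- c(10, 12, 14, 16)
  d <- describe_values(x)
  expect_equal(d$n, 4L)
  expect_equal(d$mean, 13)
  expect_equal(d$sd, sd(x))
  expect_equal(d$se, sd(x) / 2)
  expect_equal(d$cv_percent, 100 * sd(x) / 13)
  half <- qt(0.975, 3) * sd(x) / 2
  expect_equal(d$ci_lower, 13 - half)
  expect_equal(d$ci_upper, 13 + half)
})

test_that("describe_values drops NA and rejects degenerate input", {
  d <- describe_values(c(1, 2, NA, 3))
  expect_equal(d$n, 3L)
  expect_equal(d$mean, 2)
  expect_error(describe_values(5), "at least 2")
  expect_error(describe_values(c(-1, 1)), "zero")
})

test_that("the 95% CI uses the t distribution (printed-table anchor)", {
  h <- load_cohort_fixture("healthy")
  d <- describe_values(cohort_values(h, "max_pressure_SAS_BC_A"))
  # 650.0 - 2.365 * 22.1 = 597.7 as printed; the normal approximation
  # (650.0 - 1.96 * 22.1 = 606.7) would be 9 Pa off
  expect_equal(round_half_up(d$ci_lower, 1), 597.7, tolerance = 0.11)
  expect_equal(round_half_up(d$mean, 1), 650.0, tolerance = 0.05)
})

test_that("cohort_descriptives summarises every variable by group", {
  h <- load_cohort_fixture("healthy")
  d <- cohort_descriptives(h)
  expect_equal(nrow(d), 9)
  expect_true(all(d$n == 8))
  expect_true(all(c("group", "variable", "mean", "sd", "se", "cv_percent",
                    "ci_lower", "ci_upper") %in% names(d)))
})

test_that("pearson_correlation agrees with cor.test", {
  set.seed(3)
  x <- rnorm(20); y <- x + rnorm(20)
  pc <- pearson_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate))
  expect_equal(pc$p_value, ct$p.value)
  expect_equal(pc$n, 20L)
  # NA pairs are dropped
  x[1] <- NA
  expect_equal(pearson_correlation(x, y)$n, 19L)
})

test_that("shapiro_wilk wraps shapiro.test with its n limits", {
  set.seed(4)
  x <- rnorm(10)
  sw <- shapiro_wilk(x)
  st <- shapiro.test(x)
  expect_equal(sw$W, unname(st$statistic))
  expect_equal(sw$p_value, st$p.value)
  expect_error(shapiro_wilk(c(1, 2)), "3")
})

test_that("anova_tukey matches aov + TukeyHSD", {
  set.seed(5)
  dat <- data.frame(value = c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 2)),
                    group = rep(c("a", "b", "c"), each = 10))
  res <- anova_tukey(dat)
  ref <- aov(value ~ factor(group), data = dat)
  expect_equal(res$p_value, summary(ref)[[1]]$`Pr(>F)`[1])
  tk <- TukeyHSD(ref)$`factor(group)`
  expect_equal(unname(sort(res$tukey$p_adj)), sort(unname(tk[, "p adj"])))
  # named-list input is equivalent
  res2 <- anova_tukey(split(dat$value, dat$group))
  expect_equal(res2$p_value, res$p_value)
  expect_error(anova_tukey(list(a = 1:5)), "2 groups")
})

test_that("t_test_pooled matches the pooled-variance t test", {
  set.seed(6)
  x <- rnorm(12, 1); y <- rnorm(9, 0.2)
  res <- t_test_pooled(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$t, unname(ref$statistic))
  fv <- var.test(x, y)
  expect_equal(res$variance_equality_p, fv$p.value)
})

test_that("round_half_up rounds halves away from zero at printed precision", {
  expect_equal(round_half_up(36.15, 1), 36.2)
  expect_equal(round_half_up(2.25, 1), 2.3)
  expect_equal(round_half_up(-2.25, 1), -2.3)
  expect_equal(round_half_up(650.04, 1), 650.0)
})
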