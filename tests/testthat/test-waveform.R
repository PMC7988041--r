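test_that("waveform constructor validates its inputs", {
  expect_s3_class(waveform(c(0, 0.5), c(1, 2)), "csf_waveform")
  expect_error(waveform(c(0.1, 0.5), c(1, 2)), "start at time 0")
  expect_error(waveform(c(0, 0.5, 0.25), c(1, 2, 3)), "strictly increasing")
  expect_error(waveform(c(0, 1), c(1, 2), period = 1), "below the period")
  expect_error(waveform(0, 1), "length >= 2")
  expect_error(waveform(c(0, NA), c(1, 2)), "finite")
  expect_error(waveform(c(0, 0.5), c(1, 2), period = -1), "period")
})

test_that("waveforms are 1-periodic: t and t + period agree to 1e-12", {
  tt <- seq(0, 0.99, by = 0.01)
  wf <- waveform(tt, sin(2 * pi * tt) + 0.3 * cos(4 * pi * tt))
  t_query <- runif(50, 0, 1)
  expect_equal(wf_eval(wf, t_query), wf_eval(wf, t_query + 1),
               tolerance = 1e-12)
  expect_equal(wf_eval(wf, t_query), wf_eval(wf, t_query + 7),
               tolerance = 1e-12)
})

test_that("wf_eval interpolates linearly and wraps across the cycle end", {
  wf <- waveform(c(0, 0.5), c(0, 1), period = 1)
  expect_equal(wf_eval(wf, 0.25), 0.5)
  # between t = 0.5 (value 1) and t = 1 == 0 (value 0)
  expect_equal(wf_eval(wf, 0.75), 0.5)
  expect_equal(wf_eval(wf, 0), 0)
})

test_that("wf_mean is the closed trapezoidal cycle mean", {
  tt <- seq(0, 0.995, by = 0.005)
  expect_equal(wf_mean(waveform(tt, rep(3.2, length(tt)))), 3.2)
  expect_equal(wf_mean(waveform(tt, sin(2 * pi * tt))), 0, tolerance = 1e-12)
  # sampled sawtooth: mean of 0..(n-1)/n with wrap-around closure
  wf <- waveform(c(0, 0.25, 0.5, 0.75), c(0, 1, 2, 1), period = 1)
  expect_equal(wf_mean(wf), 1)
})

test_that("waveform CSV round-trip preserves samples, period and units", {
  tt <- seq(0, 0.99, by = 0.01)
  wf <- waveform(tt, 1e-7 * sin(2 * pi * tt), period = 1, units = "m3/s")
  path <- tempfile(fileext = ".csv"); on.exit(unlink(path), add = TRUE)
  write_waveform(wf, path)
  back <- read_waveform(path)
  expect_equal(back$time, wf$time)
  expect_equal(back$value, wf$value)
  expect_equal(attr(back, "period"), 1)
})

test_that("ml/min waveforms are converted to SI on read", {
  path <- tempfile(fileext = ".csv"); on.exit(unlink(path), add = TRUE)
  writeLines(c("# period_s: 1", "# units: ml/min", "time_s,value",
               "0,0.35", "0.5,0.35"), path)
  wf <- read_waveform(path)
  expect_equal(wf$value, rep(0.35 / 6e7, 2))
})

test_that("superpose_flow renormalizes to zero mean and unit peak", {
  shp <- demo_shape()
  q <- superpose_flow(shp, mean_flow = 2e-9, amplitude = 5e-9)
  expect_equal(wf_mean(q), 2e-9, tolerance = 1e-12)
  expect_equal(max(q$value), 2e-9 + 5e-9, tolerance = 1e-12)
  # a shape with nonzero mean is recentred first
  tt <- seq(0, 0.99, by = 0.01)
  biased <- waveform(tt, 5 + sin(2 * pi * tt))
  q2 <- superpose_flow(biased, 0, 1)
  expect_equal(wf_mean(q2), 0, tolerance = 1e-12)
  expect_equal(max(q2$value), 1, tolerance = 1e-9)
})
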