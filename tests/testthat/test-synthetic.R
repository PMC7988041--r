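test_that("generate_waveform is deterministic, normalized and phase-locked", {
  w1 <- generate_waveform(seed = 7)
  w2 <- generate_waveform(seed = 7)
  w3 <- generate_waveform(seed = 8)
  expect_identical(w1$value, w2$value)
  expect_false(identical(w1$value, w3$value))
  # unit peak exactly at the requested cycle fraction, zero cycle mean
  expect_equal(max(w1$value), 1)
  expect_equal(w1$time[which.max(w1$value)], 0.175)
  expect_equal(wf_mean(w1), 0, tolerance = 1e-12)
  # the peak phase is configurable
  w4 <- generate_waveform(seed = 7, phase_of_peak = 0.25, n_samples = 100)
  expect_equal(w4$time[which.max(w4$value)], 0.25)
})

test_that("generate_waveform restores the global RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_waveform(seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("cohort_spec requires a seed and validates its fields", {
  expect_error(cohort_spec(), "seed")
  expect_error(cohort_spec(seed = 1, stroke_targets_ml = c(healthy = -1, patient = 1)),
               "positive")
  spec <- cohort_spec(seed = 1)
  expect_equal(spec$n_healthy, 8)
  expect_equal(spec$n_patients, 11)
  expect_equal(unname(spec$stroke_targets_ml["patient"] /
                        spec$stroke_targets_ml["healthy"]), 7.9)
})

test_that("generate_cohort is reproducible and group-structured", {
  spec <- cohort_spec(n_healthy = 3, n_patients = 3, seed = 21)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_s3_class(a, "csf_synthetic_cohort")
  expect_equal(nrow(a), 6)
  expect_equal(sum(a$group == "healthy"), 3)
  expect_equal(a$ventricular_volume_ml, b$ventricular_volume_ml)
  expect_equal(a$amplitude_m3s, b$amplitude_m3s)
  # different seed, different draws
  c <- generate_cohort(cohort_spec(n_healthy = 3, n_patients = 3, seed = 22))
  expect_false(identical(a$ventricular_volume_ml, c$ventricular_volume_ml))
})

test_that("calibration hits the per-group stroke-volume target within 1%", {
  spec <- cohort_spec(n_healthy = 2, n_patients = 2, seed = 31)
  co <- generate_cohort(spec, calibrate = TRUE)
  for (i in seq_len(nrow(co))) {
    subj <- co[i, ]
    bc <- build_bc("C", subj$group, shape = subj$waveform[[1]],
                   amplitude = subj$amplitude_m3s)
    sim <- simulate_csf(subj, bc, mode = "FSI")
    expect_equal(stroke_volume(sim, "oscillatory"),
                 unname(spec$stroke_targets_ml[subj$group]),
                 tolerance = 0.01)
  }
})

test_that("disabling calibration does not change the sampled anatomy", {
  spec <- cohort_spec(n_healthy = 3, n_patients = 3, seed = 41)
  a <- generate_cohort(spec, calibrate = TRUE)
  b <- generate_cohort(spec, calibrate = FALSE)
  for (col in c("ventricular_volume_ml", "brain_volume_ml", "sas_volume_ml",
                "aqueduct_radius_m", "waveform_seed")) {
    expect_identical(a[[col]], b[[col]])
  }
})

test_that("volumes are truncated at +/- 3 sd of their group distribution", {
  spec <- cohort_spec(n_healthy = 150, n_patients = 150, seed = 51)
  co <- generate_cohort(spec, calibrate = FALSE)
  h <- co[co$group == "healthy", ]
  expect_true(all(abs(h$ventricular_volume_ml - 20.3) <= 3 * 0.8))
  p <- co[co$group == "patient", ]
  expect_true(all(abs(p$ventricular_volume_ml - 281.6) <= 3 * 11.5))
})

test_that("cohort_to_tables produces csf_cohort tables per group", {
  spec <- cohort_spec(n_healthy = 3, n_patients = 4, seed = 61)
  co <- generate_cohort(spec, calibrate = FALSE)
  tabs <- cohort_to_tables(co)
  expect_named(tabs, c("healthy", "patient"))
  expect_s3_class(tabs$healthy, "csf_cohort")
  expect_equal(length(unique(tabs$patient$subject)), 4)
  expect_true("ventricular_volume" %in% tabs$healthy$variable)
  # the tables feed the same statistics layer as the bundled fixtures
  d <- cohort_descriptives(tabs$patient)
  expect_true(all(d$n == 4))
})
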