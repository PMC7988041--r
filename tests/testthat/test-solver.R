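test_that("steady rigid network matches the series-resistance closed form", {
  sub <- subject_record("t1", "healthy")
  bc <- build_bc("B", "healthy", shape = flat_shape(), amplitude = 0)
  sim <- simulate_csf(sub, bc, mode = "CFD")
  lc <- last_cycle(sim)
  q0 <- 0.35 / 6e7
  el <- csfbc:::aqueduct_element(sub$aqueduct_radius_m, sub$aqueduct_length_m,
                                 fluid_properties())
  opt <- solver_options()
  expected <- 500 + q0 * (el$R + opt$r_out)
  expect_equal(mean(lc$P_ventricle), expected, tolerance = 1e-3)
  expect_equal(sd(lc$P_ventricle), 0, tolerance = 1e-12)
  expect_equal(mean(lc$Q_aqueduct), q0, tolerance = 1e-12)
})

test_that("zero inflow leaves the network at its baseline", {
  sub <- subject_record("t0", "healthy")
  bc <- build_bc("B", "healthy", shape = flat_shape(), amplitude = 0,
                 mean_inflow_ml_min = 0)
  for (mode in c("FSI", "CFD")) {
    sim <- simulate_csf(sub, bc, mode = mode)
    expect_lt(max(abs(sim$series$Q_aqueduct)), 1e-20)
    expect_equal(range(sim$series$P_ventricle), c(500, 500), tolerance = 1e-10)
    expect_equal(range(sim$series$P_sas), c(500, 500), tolerance = 1e-10)
  }
})

test_that("mass is conserved to 1e-10 of peak flow in every scheme and mode", {
  shp <- demo_shape()
  for (grp in c("healthy", "patient")) {
    sub <- subject_record(paste0("m_", grp), grp)
    for (scheme in c("A", "B", "C")) {
      bc <- build_bc(scheme, grp, shape = shp, amplitude = 5e-9)
      for (mode in c("FSI", "CFD")) {
        sim <- simulate_csf(sub, bc, mode = mode)
        expect_lt(sim$max_mass_residual, 1e-10)
      }
    }
  }
})

test_that("cycles 4 and 5 agree within 1% on default configurations", {
  shp <- demo_shape()
  for (grp in c("healthy", "patient")) {
    sub <- subject_record(paste0("p_", grp), grp)
    for (scheme in c("A", "B", "C")) {
      bc <- build_bc(scheme, grp, shape = shp, amplitude = 5e-9)
      for (mode in c("FSI", "CFD")) {
        sim <- simulate_csf(sub, bc, mode = mode)
        expect_lt(sim$cycle_periodicity, 0.01)
      }
    }
  }
})

test_that("halving dt changes the last-cycle peak pressure by <= 1%", {
  sub <- subject_record("dt", "patient")
  shp <- demo_shape()
  for (scheme in c("A", "B", "C")) {
    bc <- build_bc(scheme, "patient", shape = shp, amplitude = 5e-9)
    s1 <- simulate_csf(sub, bc, mode = "FSI", dt = 0.01)
    s2 <- simulate_csf(sub, bc, mode = "FSI", dt = 0.005)
    p1 <- max(last_cycle(s1)$P_sas)
    p2 <- max(last_cycle(s2)$P_sas)
    expect_lt(abs(p1 - p2) / abs(p2), 0.01)
  }
})

test_that("CFD mode keeps the ventricular volume rigid, FSI lets it breathe", {
  sub <- subject_record("v", "patient")
  bc <- build_bc("C", "patient", shape = demo_shape(), amplitude = 5e-9)
  pair <- run_mode_pair(sub, bc)
  expect_equal(unique(pair$cfd$series$V_ventricle), 281.6e-6)
  expect_gt(diff(range(pair$fsi$series$V_ventricle)), 0)
  cmp <- compare_runs(pair$fsi, pair$cfd)
  expect_true(all(is.finite(unlist(cmp))))
})

test_that("FSI converges to CFD as the wall becomes rigid", {
  # scheme B: with rigid walls the SAS pressure still oscillates (scheme C
  # balances prescribed in/outflows exactly, leaving it constant)
  sub <- subject_record("stiff", "patient")
  bc <- build_bc("B", "patient", shape = demo_shape(), amplitude = 5e-9)
  cfd <- simulate_csf(sub, bc, mode = "CFD")
  err <- vapply(c(1e6, 1e9), function(E) {
    stiff <- material_model(elastic_modulus = E, prony_g = numeric(0),
                            prony_tau = numeric(0))
    fsi <- simulate_csf(sub, bc, material = stiff, mode = "FSI")
    max(abs(fsi$series$P_sas - cfd$series$P_sas))
  }, numeric(1))
  scale <- diff(range(cfd$series$P_sas))
  # error shrinks with stiffness and is negligible at E = 1e9 Pa
  expect_lt(err[2], err[1])
  expect_lt(err[2] / scale, 1e-3)
})

test_that("scheme C with zero SAS compliance is rejected", {
  sub <- subject_record("c0", "healthy")
  bc <- build_bc("C", "healthy", shape = demo_shape(), amplitude = 1e-9)
  expect_error(
    simulate_csf(sub, bc, options = solver_options(sas_compliance = 0)),
    "compliance")
})

test_that("the Darcy leak pathway carries flow when enabled", {
  sub <- subject_record("leak", "patient")
  bc <- build_bc("B", "patient", shape = demo_shape(), amplitude = 5e-9)
  opt <- solver_options(darcy_leak = TRUE)
  sim <- simulate_csf(sub, bc, mode = "FSI", options = opt)
  expect_gt(max(abs(sim$series$Q_leak)), 0)
  expect_lt(sim$max_mass_residual, 1e-10)
  off <- simulate_csf(sub, bc, mode = "FSI")
  expect_equal(unique(off$series$Q_leak), 0)
})

test_that("simulation JSON round-trips", {
  sub <- subject_record("io", "healthy")
  bc <- build_bc("B", "healthy", shape = demo_shape(), amplitude = 1e-9)
  sim <- simulate_csf(sub, bc, n_cycles = 2)
  path <- tempfile(fileext = ".json"); on.exit(unlink(path))
  write_simulation_json(sim, path)
  back <- read_simulation_json(path)
  expect_equal(back$series$P_sas, sim$series$P_sas, tolerance = 1e-12)
  expect_equal(back$scheme, sim$scheme)
  expect_equal(back$mode, sim$mode)
})

test_that("subject_record validates the aqueduct radius", {
  expect_error(subject_record("bad", "healthy", aqueduct_radius_m = 5e-3),
               "aqueduct_radius_m")
  expect_error(subject_record("bad", "healthy", aqueduct_radius_m = 1e-4),
               "aqueduct_radius_m")
})
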