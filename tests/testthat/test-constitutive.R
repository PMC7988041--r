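test_that("shear modulus follows from the elastic constants", {
  expect_equal(shear_from_elastic(584.4, 0.35), 584.4 / 2.7)
  expect_equal(material_model()$shear_modulus, 584.4 / 2.7)
})

test_that("material_model validates the Prony series", {
  expect_error(material_model(prony_g = c(0.5, 0.6), prony_tau = c(1, 10)),
               "sum")
  expect_error(material_model(prony_g = c(0.1, 0.1), prony_tau = c(10, 1)),
               "increasing")
  expect_error(material_model(prony_g = 0.1, prony_tau = c(1, 2)),
               "same number")
})

test_that("relaxation modulus has the documented limits", {
  m <- material_model()
  G0 <- m$shear_modulus
  expect_equal(relaxation_modulus(0, m), G0)
  # long-time limit: G0 * (1 - 3 * 0.285) = 0.145 G0
  expect_equal(relaxation_modulus(1e7, m), 0.145 * G0, tolerance = 1e-6)
  # monotone non-increasing
  gr <- relaxation_modulus(seq(0, 2000, by = 1), m)
  expect_true(all(diff(gr) <= 0))
  expect_error(relaxation_modulus(-1, m), "t >= 0")
})

test_that("cavity step response follows Gr(t)/G0", {
  m <- material_model()
  v0 <- 2e-5
  dv <- 1e-8
  dt <- 0.05
  tt <- seq(0, 2000, by = dt)
  vol <- c(v0, rep(v0 + dv, length(tt) - 1))  # step at the first interval
  p <- cavity_transmural_pressure(vol, dt, m, v0)
  p_inst <- 4 * m$shear_modulus * dv / (3 * v0)
  # instantaneous elastic response
  expect_equal(p[2], p_inst, tolerance = 0.01)
  # relaxation tracks Gr(t)/G0 within 1% of the instantaneous value
  idx <- c(100, 1000, 10000, length(tt))
  gr <- relaxation_modulus(tt[idx] - dt, m) / m$shear_modulus
  expect_equal(p[idx] / p_inst, gr, tolerance = 0.01)
  # long-time decay toward the equilibrium modulus (Gr(2000 s) is still
  # ~1.5% above the 0.145 G0 plateau through the 410 s branch)
  gr_end <- relaxation_modulus(tt[length(tt)] - dt, m) / m$shear_modulus
  expect_equal(p[length(p)] / p_inst, gr_end, tolerance = 0.01)
  expect_lt(abs(p[length(p)] / p_inst - 0.145), 0.005)
})

test_that("cavity pressure is linear in the volume perturbation", {
  v0 <- 1e-4
  dt <- 0.01
  tt <- seq(0, 2, by = dt)
  dv <- 1e-9 * sin(2 * pi * tt)^2
  p1 <- cavity_transmural_pressure(v0 + dv, dt, v0 = v0)
  p2 <- cavity_transmural_pressure(v0 + 3 * dv, dt, v0 = v0)
  expect_equal(p2, 3 * p1, tolerance = 1e-10)
})

test_that("purely elastic material gives the algebraic cavity relation", {
  m <- elastic_material(shear = 100)
  v0 <- 1e-4
  dv <- seq(0, 1e-7, length.out = 11)
  p <- cavity_transmural_pressure(v0 + dv, dt = 0.01, material = m, v0 = v0)
  expect_equal(p, 4 * 100 * dv / (3 * v0), tolerance = 1e-12)
})

test_that("cavity pressure validates its inputs", {
  expect_error(cavity_transmural_pressure(c(1e-4, NA), 0.01), "finite")
  expect_error(cavity_transmural_pressure(c(2e-4, 2e-4), 0.01, v0 = 1e-4),
               "volume\\[1\\]")
})

test_that("darcy conductance is k A / L", {
  m <- material_model()
  expect_equal(darcy_leak_conductance(m, 0.05, 1e-3),
               m$permeability * 1e-3 / 0.05)
  expect_error(darcy_leak_conductance(m, 0, 1e-3), "path_length")
})

test_that("fluid properties default to CSF-like water", {
  fl <- fluid_properties()
  expect_equal(fl$density, 998.2)
  expect_equal(fl$viscosity, 0.001)
  expect_error(fluid_properties(density = -1), "density")
})
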