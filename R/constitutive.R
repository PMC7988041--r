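#' CSF fluid properties
#'
#' CSF is treated as a Newtonian fluid with the properties of water at
#' 37 degrees C.
#'
#' @param density Fluid density, kg/m^3 (default 998.2).
#' @param viscosity Dynamic viscosity, kg m^-1 s^-1 (default 0.001).
#' @return A `csf_fluid` list.
#' @export
fluid_properties <- function(density = 998.2, viscosity = 0.001) {
  check_number(density, "density", lower = 0, strict_lower = TRUE)
  check_number(viscosity, "viscosity", lower = 0, strict_lower = TRUE)
  structure(list(density = density, viscosity = viscosity, newtonian = TRUE),
            class = "csf_fluid")
}

#' Poro-viscoelastic brain-tissue material model
#'
#' Brain parenchyma is modelled as a linear viscoelastic solid whose shear
#' relaxation is a three-branch Prony series,
#' \deqn{G_r(t) = G_0 \left(1 - \sum_k g_k (1 - e^{-t/\tau_k})\right),}
#' with an optional Darcy permeability for a trans-parenchymal leak pathway.
#' Defaults are the standard hydrocephalus brain-tissue parameters:
#' E = 584.4 Pa, Poisson ratio 0.35, g_k = 0.285 for each branch (the
#' literature source gives a single g for all three branches),
#' tau = (3.1, 27, 410) s, void ratio 0.2, permeability 4.08e-12 m^4/(N s).
#'
#' @param elastic_modulus Drained elastic modulus E, Pa.
#' @param poisson_ratio Poisson ratio, in `[0, 0.5)`.
#' @param prony_g Dimensionless branch moduli g_k; their sum must be < 1 so
#'   the long-time modulus stays positive.
#' @param prony_tau Relaxation times tau_k in s, strictly increasing.
#' @param void_ratio Porous void ratio (dimensionless).
#' @param permeability Darcy permeability, m^4/(N s).
#' @return A `csf_material` list; `$shear_modulus` holds the instantaneous
#'   shear modulus G0 = E / (2 (1 + nu)).
#' @examples
#' mat <- material_model()
#' mat$shear_modulus                   # 216.44 Pa
#' relaxation_modulus(c(0, 1e6), mat)  # G0 and the long-time plateau
#' @export
material_model <- function(elastic_modulus = 584.4,
                           poisson_ratio = 0.35,
                           prony_g = c(0.285, 0.285, 0.285),
                           prony_tau = c(3.1, 27, 410),
                           void_ratio = 0.2,
                           permeability = 4.08e-12) {
  check_number(elastic_modulus, "elastic_modulus", lower = 0)
  if (length(prony_g) != length(prony_tau)) {
    abort("prony_g and prony_tau must have the same number of branches.")
  }
  if (any(prony_g < 0) || sum(prony_g) >= 1) {
    abort("prony_g must be non-negative with sum < 1 (positive long-time modulus).")
  }
  if (length(prony_tau) > 0 && (any(prony_tau <= 0) || any(diff(prony_tau) <= 0))) {
    abort("prony_tau must be positive and strictly increasing.")
  }
  check_number(void_ratio, "void_ratio", lower = 0)
  check_number(permeability, "permeability", lower = 0)
  structure(list(
    elastic_modulus = elastic_modulus,
    poisson_ratio = poisson_ratio,
    shear_modulus = shear_from_elastic(elastic_modulus, poisson_ratio),
    prony_g = as.numeric(prony_g),
    prony_tau = as.numeric(prony_tau),
    void_ratio = void_ratio,
    permeability = permeability
  ), class = "csf_material")
}

#' Instantaneous shear modulus from (E, nu)
#'
#' Standard isotropic elasticity: G0 = E / (2 (1 + nu)).
#'
#' @param elastic_modulus E in Pa, non-negative.
#' @param poisson_ratio nu in (-1, 0.5); the incompressible limit nu = 0.5
#'   is rejected.
#' @return G0 in Pa.
#' @export
shear_from_elastic <- function(elastic_modulus, poisson_ratio) {
  check_number(elastic_modulus, "elastic_modulus", lower = 0)
  check_number(poisson_ratio, "poisson_ratio", lower = -1, upper = 0.5,
               strict_lower = TRUE, strict_upper = TRUE)
  elastic_modulus / (2 * (1 + poisson_ratio))
}

#' Shear relaxation modulus Gr(t)
#'
#' @param t Times in s, all non-negative (vectorised).
#' @param material A [material_model()].
#' @return Gr(t) in Pa; monotone non-increasing from G0 at t = 0 to
#'   G0 (1 - sum g_k) as t grows.
#' @export
relaxation_modulus <- function(t, material = material_model()) {
  if (any(t < 0)) abort("relaxation_modulus requires t >= 0.")
  g <- material$prony_g
  tau <- material$prony_tau
  G0 <- material$shear_modulus
  if (length(g) == 0) return(rep(G0, length(t)))
  decay <- vapply(t, function(ti) sum(g * (1 - exp(-ti / tau))), numeric(1))
  G0 * (1 - decay)
}

#' Transmural pressure of a viscoelastic spherical cavity
#'
#' Maps a ventricular volume history V(t) to the transmural pressure that
#' the surrounding viscoelastic parenchyma exerts.  For a pressurised
#' spherical cavity in an unbounded incompressible-shear medium the elastic
#' relation is dV/V0 = 3 dP / (4 G); the viscoelastic extension by the
#' correspondence principle is the hereditary integral
#' \deqn{P(t) = \frac{4}{3 V_0} \int_0^t G_r(t - s)\, \dot V(s)\, ds,}
#' evaluated with an exact exponential-integrator recursion per Prony
#' branch (O(1) memory, unconditionally stable, first-order accurate for a
#' volume rate held constant over each step).
#'
#' @param volume Sampled volume history V(t) in m^3 on a uniform grid with
#'   spacing `dt`; `volume[1]` must equal `v0` (zero initial deviation).
#' @param dt Uniform time step in s.
#' @param material A [material_model()].
#' @param v0 Reference cavity volume in m^3 (> 0).
#' @return Transmural pressure history in Pa, same length as `volume`.
#' @export
cavity_transmural_pressure <- function(volume, dt, material = material_model(),
                                       v0 = volume[1]) {
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(v0, "v0", lower = 0, strict_lower = TRUE)
  if (length(volume) < 1L || !all(is.finite(volume))) {
    abort("volume history must be finite.")
  }
  if (abs(volume[1] - v0) > 1e-12 * v0) {
    abort("volume[1] must equal v0 (zero initial volume deviation).")
  }
  st <- prony_state_init(material, v0)
  n <- length(volume)
  p <- numeric(n)
  p[1] <- 0
  for (i in seq_len(n - 1L)) {
    st <- prony_state_step(st, volume[i + 1L] - volume[i], dt)
    p[i + 1L] <- prony_state_pressure(st, volume[i + 1L])
  }
  p
}

# --- Prony internal-variable state --------------------------------------
# One internal variable per (g_k, tau_k) branch.  Writing
#   Gr(t) = G_inf + sum_k G0 g_k exp(-t/tau_k),  G_inf = G0 (1 - sum g_k),
# the hereditary integral splits into an equilibrium part proportional to
# the accumulated volume deviation and per-branch convolutions h_k that obey
#   h_k(t) = int_0^t G0 g_k exp(-(t-s)/tau_k) Vdot(s) ds.
# With Vdot constant over a step the update is exact:
#   h_k <- e_k h_k + G0 g_k (dV/dt) tau_k (1 - e_k),  e_k = exp(-dt/tau_k).

prony_state_init <- function(material, v0) {
  list(material = material, v0 = v0,
       h = numeric(length(material$prony_g)))
}

prony_state_step <- function(state, dvol, dt) {
  m <- state$material
  if (length(m$prony_g) > 0) {
    ek <- exp(-dt / m$prony_tau)
    state$h <- ek * state$h +
      m$shear_modulus * m$prony_g * (dvol / dt) * m$prony_tau * (1 - ek)
  }
  state
}

prony_state_pressure <- function(state, volume) {
  m <- state$material
  g_inf <- m$shear_modulus * (1 - sum(m$prony_g))
  (4 / (3 * state$v0)) * (g_inf * (volume - state$v0) + sum(state$h))
}

#' Darcy conductance of a porous leak pathway
#'
#' Darcy's law for flow through a porous slab: Q = k A dP / L, so the
#' pathway conductance is k A / L with the permeability k in m^4/(N s).
#'
#' @param material A [material_model()] (supplies the permeability).
#' @param path_length Pathway length L in m (> 0).
#' @param path_area Pathway cross-section A in m^2 (>= 0).
#' @return Conductance in m^3/(s Pa).
#' @export
darcy_leak_conductance <- function(material = material_model(),
                                   path_length, path_area) {
  check_number(path_length, "path_length", lower = 0, strict_lower = TRUE)
  check_number(path_area, "path_area", lower = 0)
  material$permeability * path_area / path_length
}
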