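#' Womersley oscillatory velocity profile in a rigid tube
#'
#' Analytic axial velocity for fully developed oscillatory flow driven by a
#' sinusoidal axial pressure gradient `G cos(omega t)` (Pa/m) in a rigid
#' circular duct of radius `a`:
#' \deqn{u(r,t) = \Re\left\{ \frac{G}{i\rho\omega}
#'   \left[1 - \frac{J_0(i^{3/2}\alpha r/a)}{J_0(i^{3/2}\alpha)}\right]
#'   e^{i\omega t} \right\},}
#' with Womersley number `alpha = a sqrt(omega rho / mu)`.  The no-slip wall
#' condition `u(a, t) = 0` holds exactly, and for `alpha -> 0` the profile
#' collapses onto the quasi-static Poiseuille parabola
#' `G (a^2 - r^2) cos(omega t) / (4 mu)`.  This is the analytic oracle for
#' the aqueduct resistance-inertance element.
#'
#' @param r Radial positions, m, each in `[0, a]`.
#' @param t Time, s (scalar or same length as `r`).
#' @param a Tube radius, m.
#' @param omega Angular frequency, rad/s (> 0).
#' @param gradient_amplitude Pressure-gradient amplitude G, Pa/m.
#' @param fluid A [fluid_properties()].
#' @return Axial velocity in m/s.
#' @export
womersley_velocity <- function(r, t, a, omega, gradient_amplitude,
                               fluid = fluid_properties()) {
  check_number(a, "a", lower = 0, strict_lower = TRUE)
  check_number(omega, "omega", lower = 0, strict_lower = TRUE)
  if (any(r < 0) || any(r > a)) abort("radial positions must satisfy 0 <= r <= a.")
  rho <- fluid$density; mu <- fluid$viscosity
  alpha <- a * sqrt(omega * rho / mu)
  lam <- alpha * exp(3i * pi / 4)  # i^{3/2} alpha
  j0a <- besselJ_complex(lam, 0L)
  # subtract before dividing, with the argument built from the exact ratio
  # r/a: at r == a the numerator cancels to 0 exactly, so no-slip holds to
  # the bit (1 - J0(z)/J0(z) would leave ~1e-17 of division roundoff)
  prof <- (j0a - besselJ_complex(lam * (r / a), 0L)) / j0a
  Re((gradient_amplitude / (1i * rho * omega)) * prof * exp(1i * omega * t))
}

#' Womersley volumetric flow amplitude (complex)
#'
#' Cross-section integral of the Womersley profile for a unit-phase
#' gradient `G e^{i omega t}`: the complex flow amplitude
#' `Q_hat = (G pi a^2 / (i rho omega)) [1 - 2 J1(L)/(L J0(L))]` with
#' `L = i^{3/2} alpha`.  Used to map flow harmonics back to velocity
#' profiles and to cross-check the duct element's frequency response.
#'
#' @inheritParams womersley_velocity
#' @return Complex flow amplitude, m^3/s.
#' @export
womersley_flow_amplitude <- function(a, omega, gradient_amplitude,
                                     fluid = fluid_properties()) {
  rho <- fluid$density
  alpha <- a * sqrt(omega * rho / fluid$viscosity)
  lam <- alpha * exp(3i * pi / 4)
  shape <- 1 - 2 * besselJ_complex(lam, 1L) / (lam * besselJ_complex(lam, 0L))
  (gradient_amplitude * pi * a^2 / (1i * rho * omega)) * shape
}

#' Peak aqueduct velocity from a simulated flow series
#'
#' Converts the last-cycle aqueduct flow of a simulation into a peak axial
#' velocity.  Method `"poiseuille"` uses the parabolic-profile factor,
#' `u_max = 2 |Q|_max / (pi a^2)`; method `"womersley"` Fourier-decomposes
#' the last cycle and reconstructs the centreline velocity from the
#' per-harmonic Womersley profile, which accounts for the flattening and
#' phase lag of oscillatory flow.
#'
#' @param sim A `csf_sim` from [simulate_csf()].
#' @param a Aqueduct radius in m (defaults to the simulated subject's).
#' @param fluid A [fluid_properties()].
#' @param method `"poiseuille"` or `"womersley"`.
#' @param n_harmonics Harmonics retained by the Womersley reconstruction.
#' @return Peak velocity in m/s.
#' @export
peak_aqueduct_velocity <- function(sim, a = sim$aqueduct_radius_m,
                                   fluid = fluid_properties(),
                                   method = c("poiseuille", "womersley"),
                                   n_harmonics = 20) {
  method <- match.arg(method)
  stopifnot(inherits(sim, "csf_sim"))
  lc <- last_cycle(sim)
  q <- lc$Q_aqueduct
  area <- pi * a^2
  if (method == "poiseuille") {
    return(2 * max(abs(q)) / area)
  }
  n <- length(q)
  co <- fft(q) / n
  nh <- min(n_harmonics, floor((n - 1) / 2))
  rho <- fluid$density; mu <- fluid$viscosity
  tt <- lc$time
  u <- rep(Re(co[1]) * 2 / area, n)  # steady part: Poiseuille centreline
  for (m in seq_len(nh)) {
    om <- 2 * pi * m / sim$period
    alpha <- a * sqrt(om * rho / mu)
    lam <- alpha * exp(3i * pi / 4)
    j0 <- besselJ_complex(lam, 0L)
    j1 <- besselJ_complex(lam, 1L)
    # centreline velocity per unit flow for this harmonic
    ratio <- (1 - 1 / j0) / (1 - 2 * j1 / (lam * j0)) / area
    u <- u + 2 * Re(co[m + 1L] * ratio * exp(2i * pi * m * tt / sim$period))
  }
  max(abs(u))
}
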