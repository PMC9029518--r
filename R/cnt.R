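#' Classical nucleation theory parameter set
#'
#' Bundles the physical inputs of the homogeneous-nucleation formulas:
#' interfacial tension between the solid nucleus and the solution,
#' molecular volume inside the nucleus, temperature and the kinetic
#' prefactor of the nucleation rate.
#'
#' @param gamma Interfacial tension, N/m (> 0).
#' @param omega Molecular volume, m^3 (> 0).
#' @param temperature Temperature, K (> 0). Default 298.15.
#' @param prefactor Kinetic prefactor An, 1/(m^3 s) (> 0). Default 1e30,
#'   a typical order of magnitude; the study gives no value.
#' @return List of class `cnt_params`.
#' @examples
#' p <- cnt_params(gamma = 0.01, omega = 5e-28)
#' critical_radius(p, beta = 10)
#' @export
cnt_params <- function(gamma, omega,
                       temperature = nanoprecip_constants()$temperature,
                       prefactor = nanoprecip_constants()$prefactor) {
  .assert_scalar_num(gamma, "gamma", positive = TRUE)
  .assert_scalar_num(omega, "omega", positive = TRUE)
  .assert_scalar_num(temperature, "temperature", positive = TRUE)
  .assert_scalar_num(prefactor, "prefactor", positive = TRUE)
  structure(list(gamma = gamma, omega = omega, temperature = temperature,
                 prefactor = prefactor),
            class = "cnt_params")
}

.check_beta_above_one <- function(beta) {
  if (any(!is.finite(beta)) || any(beta <= 1)) {
    .np_abort("`beta` must be > 1: below saturation there is no finite nucleation barrier.",
              class = "nanoprecip_domain_error")
  }
}

#' Critical free-energy barrier of nucleation
#'
#' The work needed to assemble a critical nucleus from a supersaturated
#' solution,
#' deltaG* = 16 pi gamma^3 Omega^2 / (3 kB^2 T^2 (ln beta)^2):
#' it falls with supersaturation, rises steeply (cubically) with
#' interfacial tension, and diverges as beta approaches 1 from above.
#'
#' @param params A [cnt_params()] object.
#' @param beta Supersaturation ratio, > 1 (vectorized).
#' @return Barrier height, J.
#' @examples
#' critical_energy(cnt_params(0.01, 5e-28), beta = 10)  # 4.663e-20 J
#' @export
critical_energy <- function(params, beta) {
  .check_beta_above_one(beta)
  kB <- .kB
  with(params,
       16 * pi * gamma^3 * omega^2 /
         (3 * kB^2 * temperature^2 * log(beta)^2))
}

#' Critical nucleus radius
#'
#' r* = 2 Omega gamma / (kB T ln beta): embryos above this radius grow,
#' smaller ones redissolve. Decreases with supersaturation and is
#' linear in the interfacial tension.
#'
#' @inheritParams critical_energy
#' @return Radius, m.
#' @examples
#' critical_radius(cnt_params(0.01, 5e-28), beta = 10)  # 1.055e-9 m
#' @export
critical_radius <- function(params, beta) {
  .check_beta_above_one(beta)
  with(params, 2 * omega * gamma / (.kB * temperature * log(beta)))
}

#' Homogeneous nucleation rate
#'
#' J = An exp(-deltaG* / (kB T)): an Arrhenius-type law whose exponent
#' is the critical barrier in thermal units. It rises steeply with
#' supersaturation and approaches the prefactor An asymptotically as
#' beta grows; at or below saturation (beta <= 1) the rate is defined
#' as zero so that staged-addition simulations can pass through
#' undersaturated early portions.
#'
#' @inheritParams critical_energy
#' @param beta Supersaturation ratio, > 0 (vectorized); values <= 1
#'   return 0.
#' @return Nucleation rate, 1/(m^3 s).
#' @examples
#' nucleation_rate(cnt_params(0.01, 5e-28, prefactor = 1), beta = 10)
#' @export
nucleation_rate <- function(params, beta) {
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    .np_abort("`beta` must be > 0.", class = "nanoprecip_input_error")
  }
  out <- numeric(length(beta))
  sup <- beta > 1
  if (any(sup)) {
    dg <- critical_energy(params, beta[sup])
    out[sup] <- params$prefactor *
      exp(-dg / (.kB * params$temperature))
  }
  out
}

#' Smoluchowski rapid-coagulation rate constant
#'
#' Diffusion-limited collision kernel for equal spheres in a quiescent
#' medium, ks = 8 kB T / (3 mu), with mu the dynamic viscosity. The
#' particle radius cancels for equal-size collisions, so the kernel is
#' size-independent.
#'
#' @param temperature Temperature, K.
#' @param viscosity Dynamic viscosity, Pa s.
#' @return Rate constant, m^3/s.
#' @examples
#' smoluchowski_rate_constant(298.15, 8.872e-4)  # 1.237e-17 m^3/s
#' @export
smoluchowski_rate_constant <- function(temperature = nanoprecip_constants()$temperature,
                                       viscosity = nanoprecip_constants()$viscosity) {
  .assert_scalar_num(temperature, "temperature", positive = TRUE)
  .assert_scalar_num(viscosity, "viscosity", positive = TRUE)
  8 * .kB * temperature / (3 * viscosity)
}

#' Particle collision (aggregation) rate
#'
#' Second-order Smoluchowski law rs = ks np^2: the volumetric rate of
#' pairwise particle encounters in a suspension with number density np.
#'
#' @param ks Rate constant, m^3/s (see
#'   [smoluchowski_rate_constant()]).
#' @param np Particle number density, 1/m^3 (>= 0, vectorized).
#' @return Collision rate, 1/(m^3 s).
#' @examples
#' collision_rate(1.237e-17, 1e15)
#' @export
collision_rate <- function(ks, np) {
  if (any(np < 0)) {
    .np_abort("`np` must be >= 0.", class = "nanoprecip_input_error")
  }
  ks * np^2
}
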