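#' Physical constants and package defaults
#'
#' `nanoprecip_constants()` returns the fixed physical constants and the
#' package-wide numerical defaults used by the model chain.
#'
#' @return A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, 1.380649e-23 J/K (exact, SI).}
#'   \item{N_A}{Avogadro constant, 6.02214076e23 1/mol (exact, SI).}
#'   \item{pKw}{Default water ionic-product exponent, 14.0 (25 degC).}
#'   \item{temperature}{Default process temperature, 298.15 K.}
#'   \item{viscosity}{Default medium dynamic viscosity, 8.872e-4 Pa s
#'     (water at 25 degC as configured on the light-scattering instrument).}
#'   \item{prefactor}{Default nucleation-rate kinetic prefactor An,
#'     1e30 1/(m^3 s), a typical classical-nucleation-theory order of
#'     magnitude.}
#'   \item{gamma_floor}{Lower clamp for the effective interfacial tension,
#'     1e-4 N/m.}
#' }
#' @examples
#' nanoprecip_constants()$kB
#' @export
nanoprecip_constants <- function() {
  list(
    kB          = 1.380649e-23,
    N_A         = 6.02214076e23,
    pKw         = 14.0,
    temperature = 298.15,
    viscosity   = 8.872e-4,
    prefactor   = 1e30,
    gamma_floor = 1e-4
  )
}

# internal shorthands
.kB  <- 1.380649e-23
.N_A <- 6.02214076e23
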