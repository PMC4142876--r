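# Physical constants (CODATA), in the package unit system: nm, kJ/mol, K.

## Coulomb constant for two unit charges, e^2 * N_A / (4 pi eps0), kJ mol^-1 nm
.COULOMB_KJ_NM <- 138.935458

## Gas constant, kJ mol^-1 K^-1
.KB_KJ <- 0.008314462618

## Faraday constant, C mol^-1, and vacuum permittivity, F m^-1 (SI, used for
## the Debye screening parameter only)
.FARADAY <- 96485.33212
.EPS0 <- 8.8541878128e-12
.RGAS_SI <- 8.314462618

#' Thermal energy in kJ/mol
#'
#' @param temperature temperature in kelvin.
#' @return \code{kT} in kJ/mol (\code{2.478} at 298 K).
#' @examples
#' kT(298)
#' @export
kT <- function(temperature = 298) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .KB_KJ * temperature
}

#' Inverse Debye screening length
#'
#' Debye parameter \eqn{\kappa} for a 1:1 electrolyte of the stated ionic
#' strength in a medium of the stated relative dielectric constant.
#'
#' @param ionicStrength ionic strength in mol/L; 0 switches screening off.
#' @param dielectric relative dielectric constant of the medium.
#' @param temperature temperature in kelvin.
#' @return \eqn{\kappa} in nm^-1 (about 1.03 nm^-1 in water at 0.1 M, 298 K).
#' @examples
#' debyeKappa(0.1, 80, 298)
#' @export
debyeKappa <- function(ionicStrength, dielectric, temperature = 298) {
  stopifnot(ionicStrength >= 0, dielectric > 0, temperature > 0)
  if (ionicStrength == 0) return(0)
  kap_m <- sqrt(2 * .FARADAY^2 * (ionicStrength * 1000) /
                  (.EPS0 * dielectric * .RGAS_SI * temperature))
  kap_m * 1e-9
}

#' Screened-Coulomb site-site interaction in pK units
#'
#' Interaction free energy of two unit positive charges at distance \code{r}
#' in a dielectric continuum with Debye screening, expressed in pK units
#' (kJ/mol divided by \code{kT ln 10}).  This is the pairwise surrogate used
#' in place of a finite-difference Poisson-Boltzmann solve.
#'
#' @param r distance in nm (must be positive).
#' @param dielectric relative dielectric constant.
#' @param ionicStrength ionic strength in mol/L.
#' @param temperature temperature in kelvin.
#' @return interaction energy in pK units, always >= 0.
#' @examples
#' screenedCoulombPK(0.5, 80, 0.1, 298)
#' @export
screenedCoulombPK <- function(r, dielectric = 80, ionicStrength = 0.1,
                              temperature = 298) {
  stopifnot(all(r > 0), dielectric > 0, ionicStrength >= 0)
  kap <- debyeKappa(ionicStrength, dielectric, temperature)
  kTln10 <- kT(temperature) * log(10)
  .COULOMB_KJ_NM * exp(-kap * r) / (dielectric * r) / kTln10
}

## Run an expression under a local, restored RNG state.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
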