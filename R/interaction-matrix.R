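# Screened-Coulomb surrogate for the Poisson-Boltzmann site-site energies.

## Geometry sanity floor for site-site distances, nm (an amine pair closer
## than this signals an unphysical conformation).
.SITE_DIST_FLOOR <- 0.1

#' Site-site interaction matrix from a conformation
#'
#' Surrogate for the Poisson-Boltzmann pairwise terms: unit positive charges
#' on the six amine nitrogens interacting through a screened Coulomb
#' potential,
#' \deqn{W_{ij} = C \exp(-\kappa r_{ij}) / (\epsilon_r r_{ij}) / (kT \ln 10),}
#' with \eqn{C} the Coulomb constant for unit charges (kJ/mol nm), \eqn{\kappa}
#' the Debye parameter for the stated ionic strength and temperature, and
#' \eqn{r_{ij}} the amine-nitrogen inter-site distance.  Entries are in pK
#' units, non-negative (like charges repel), symmetric with zero diagonal.
#'
#' @param conf a \linkS4class{Conformation} containing all six amine
#'   nitrogens.
#' @param solventDielectric relative dielectric constant (default 80, the
#'   aqueous solvent value used for the electrostatics).
#' @param ionicStrength mol/L (default 0.1).
#' @param temperature kelvin (default 298).
#' @return symmetric 6 x 6 matrix in pK units, dimnames = site labels.
#' @examples
#' conf <- generateConformation(0.5, seed = 1)
#' W <- computeInteractionMatrix(conf)
#' max(abs(W - t(W)))  # 0
#' @export
computeInteractionMatrix <- function(conf, solventDielectric = 80,
                                     ionicStrength = 0.1,
                                     temperature = 298) {
  stopifnot(is(conf, "Conformation"), solventDielectric > 0,
            ionicStrength >= 0, temperature > 0)
  topo <- conf@topology
  N <- coords(conf, paste0("N.", topo@sites))
  .interactionMatrixFromSites(N, topo@sites, solventDielectric,
                              ionicStrength, temperature)
}

## Shared fast path: takes the 6 x 3 amine coordinate matrix directly.
.interactionMatrixFromSites <- function(N, sites, solventDielectric,
                                        ionicStrength, temperature) {
  D <- as.matrix(dist(N))
  off <- D[upper.tri(D)]
  if (any(off < .SITE_DIST_FLOOR))
    stop(sprintf(
      "unphysical conformation: amine-amine distance %.3f nm below %.2f nm",
      min(off), .SITE_DIST_FLOOR))
  W <- matrix(0, nrow(N), nrow(N), dimnames = list(sites, sites))
  W[upper.tri(W)] <- screenedCoulombPK(off, solventDielectric,
                                       ionicStrength, temperature)
  W + t(W)
}
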