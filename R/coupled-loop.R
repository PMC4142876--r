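# Stop-and-go protonation/conformation coupling.
#
# Each cycle alternates (i) a titration Monte Carlo run on the current
# conformation's interaction matrix, keeping the last sampled protonation
# state, and (ii) a conformational Metropolis move in the openness order
# parameter, accepted on an energy that combines the Coulomb repulsion of
# the current protonation state with a mild packing preference for closed
# arms.  This re-expresses the stop-and-go constant-pH scheme with a
# conformational MC stage in place of molecular dynamics.

## Packing (hydrophobic) preference for closed arms, pK units per unit
## openness: the neutral receptor favours compact conformations.
.CONF_CLOSED_BIAS <- 1.2
## Conformational-energy Coulomb parameters: intramolecular repulsion acts
## partly through the low-dielectric solute interior, so it is evaluated at
## an effective dielectric of 20 with weak screening (0.01 M), while the
## titration energetics keep the aqueous solvent parameters (80, 0.1 M).
.CONF_DIELECTRIC <- 20
.CONF_IONIC <- 0.01

## Conformational energy (pK units) of an openness value under protonation
## state s: closed-bias plus screened-Coulomb repulsion between the
## protonated amine nitrogens (ideal geometry fast path).
.conformationalEnergy <- function(openness, state,
                                  closedBias = .CONF_CLOSED_BIAS) {
  e <- closedBias * openness
  idx <- which(state == 1)
  if (length(idx) >= 2) {
    N <- .amineCoordsFast(openness)[idx, , drop = FALSE]
    r <- dist(N)
    e <- e + sum(screenedCoulombPK(r, .CONF_DIELECTRIC, .CONF_IONIC))
  }
  e
}

#' Default conformational proposal: reflected Gaussian random walk
#'
#' @param sd random-walk step size in openness units (default 0.08).
#' @return a function \code{openness -> proposal} usable as the
#'   \code{confMover} of \code{\link{coupledCpHLoop}}.
#' @export
opennessRandomWalk <- function(sd = 0.08) {
  force(sd)
  function(openness) {
    x <- openness + rnorm(1, 0, sd)
    ## reflect into [0, 1]
    x <- abs(x)
    if (x > 1) x <- 2 - x
    min(max(x, 0), 1)
  }
}

#' Null conformational mover (frozen conformation)
#' @return a function that always proposes the current openness.
#' @export
frozenMover <- function() function(openness) openness

#' Coupled protonation/conformation constant-pH loop
#'
#' Desk-scale stop-and-go scheme: each cycle (i) rebuilds the titration
#' model from the current conformation via \code{modelBuilder}, runs a
#' short titration MC and keeps the last sampled protonation state, then
#' (ii) makes \code{confMovesPerCycle} Metropolis proposals in openness
#' (via \code{confMover}) accepted with probability
#' \eqn{\min(1, 10^{-\Delta E})} on the conformational energy of the
#' current state.  The joint (conformation, protonation) trajectory is
#' returned; all randomness is reproducible under \code{seed}.
#'
#' @param pH the pH.
#' @param nCycles number of coupled cycles (>= 1).
#' @param seed integer seed.
#' @param modelBuilder function \code{Conformation -> TitrationModel}
#'   (default \code{\link{titrationModelFromConformation}}).
#' @param confMover openness proposal function (default
#'   \code{\link{opennessRandomWalk}()}).
#' @param mcStepsPerCycle titration MC steps per cycle (default 1000; the
#'   reference protocol uses 1e5 per protonation update, scaled down here
#'   for desk-scale runs).
#' @param confMovesPerCycle conformational proposals per cycle (default 5).
#' @param initialOpenness starting openness (default 0.5).
#' @param closedBias packing preference for closed arms, pK units per unit
#'   openness (default 1.2).
#' @param noise per-arm jitter of the stored conformations, nm (default 0:
#'   the loop samples the ideal-geometry openness coordinate).
#' @param fixedState optional 0/1 vector: freeze the protonation state and
#'   skip the titration stage (conformational sampling at constant
#'   protonation, e.g. the aprotic regime).
#' @return an \linkS4class{EnsembleRecord} with one frame and one
#'   protonation state per cycle; \code{metadata$openness} traces the
#'   order parameter.
#' @examples
#' ens <- coupledCpHLoop(pH = 6, nCycles = 5, seed = 1,
#'                       mcStepsPerCycle = 200)
#' nFrames(ens)
#' @export
coupledCpHLoop <- function(pH, nCycles, seed,
                           modelBuilder = titrationModelFromConformation,
                           confMover = opennessRandomWalk(),
                           mcStepsPerCycle = 1000,
                           confMovesPerCycle = 5,
                           initialOpenness = 0.5,
                           closedBias = .CONF_CLOSED_BIAS,
                           noise = 0, fixedState = NULL) {
  if (!is.numeric(nCycles) || nCycles < 1) stop("'nCycles' must be >= 1")
  nCycles <- as.integer(nCycles)
  stopifnot(!missing(seed))
  withSeed(seed, {
    openness <- initialOpenness
    state <- integer(6)
    coordsList <- vector("list", nCycles)
    states <- vector("list", nCycles)
    opennessTrace <- numeric(nCycles)
    template <- NULL
    for (cyc in seq_len(nCycles)) {
      frameSeed <- sample.int(.Machine$integer.max - 1L, 1)
      conf <- generateConformation(openness, frameSeed, noise = noise)
      if (is.null(template)) template <- conf
      ## (i) titration stage on the frozen conformation
      if (is.null(fixedState)) {
        model <- modelBuilder(conf)
        mcSeed <- sample.int(.Machine$integer.max - 1L, 1)
        res <- mcSampleStates(model@pKint, model@W, pH,
                              nSteps = mcStepsPerCycle, seed = mcSeed,
                              startState = state)
        state <- as.integer(res$finalState)
      } else {
        state <- as.integer(fixedState)
      }
      ## (ii) conformational stage at the fixed protonation state
      eCur <- .conformationalEnergy(openness, state, closedBias)
      for (k in seq_len(confMovesPerCycle)) {
        prop <- confMover(openness)
        eProp <- .conformationalEnergy(prop, state, closedBias)
        if (eProp - eCur <= 0 || runif(1) < 10^(-(eProp - eCur))) {
          openness <- prop
          eCur <- eProp
        }
      }
      coordsList[[cyc]] <- generateConformation(openness, frameSeed,
                                                noise = noise)@coords
      states[[cyc]] <- state
      opennessTrace[cyc] <- openness
    }
    new("EnsembleRecord", template = template, coordsList = coordsList,
        states = states, frames = seq_len(nCycles),
        metadata = list(pH = pH, seed = seed, openness = opennessTrace,
                        mcStepsPerCycle = mcStepsPerCycle,
                        closedBias = closedBias))
  })
}
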