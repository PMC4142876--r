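# S4 classes for the receptor model, titration engine and analyses.

## Minimum allowed distance between any two atoms, nm.
.DIST_FLOOR <- 0.05
## Maximum out-of-plane deviation tolerated for the phenyl ring, nm.
.RING_PLANARITY_TOL <- 1e-3

#' ReceptorTopology: the 3-arm, 6-site labelled graph of titratable amines
#'
#' The receptor carries a central phenyl ring and three identical arms; each
#' arm has one pyrrolic nitrogen and two titratable secondary amines, the
#' first generation near the core and the second generation at the arm tip.
#' The arm permutation group acts on the six sites preserving generation
#' labels.
#'
#' @slot nArms number of arms (3).
#' @slot sites character vector of six site labels, generation-1 sites first.
#' @slot arm integer arm index (1..3) of each site.
#' @slot generation integer generation (1 or 2) of each site.
#' @slot pyrrolicAtoms atom labels of the three pyrrolic nitrogens.
#' @slot ringAtoms atom labels of the six phenyl ring atoms.
#' @export
setClass("ReceptorTopology",
  representation(nArms = "integer", sites = "character", arm = "integer",
                 generation = "integer", pyrrolicAtoms = "character",
                 ringAtoms = "character"),
  validity = function(object) {
    msg <- character()
    if (object@nArms != 3L) msg <- c(msg, "receptor must have 3 arms")
    if (length(object@sites) != 6L) msg <- c(msg, "exactly 6 titratable sites required")
    if (!all(sort(unique(object@generation)) == c(1L, 2L)))
      msg <- c(msg, "generations must be 1 and 2")
    tab <- table(object@arm, object@generation)
    if (!all(dim(tab) == c(3L, 2L)) || !all(tab == 1L))
      msg <- c(msg, "each arm must carry exactly one site per generation")
    if (length(object@pyrrolicAtoms) != 3L) msg <- c(msg, "3 pyrrolic atoms required")
    if (length(object@ringAtoms) != 6L) msg <- c(msg, "6 ring atoms required")
    if (anyDuplicated(object@sites)) msg <- c(msg, "site labels must be unique")
    if (length(msg)) msg else TRUE
  })

#' Conformation: labelled 3-D coordinates of receptor (and optional ligand)
#'
#' Coordinates in nm for the coarse bead model: 6 phenyl ring atoms, 3
#' pyrrolic nitrogens and 6 amine nitrogens (plus their polar hydrogens),
#' optionally followed by a bound mannoside mimic (6 sugar-ring atoms,
#' hydroxyl/glycosidic oxygens with hydrogens, 8 tail carbons).
#'
#' @slot coords numeric matrix (n x 3), rownames are atom labels.
#' @slot atoms data.frame with columns \code{label}, \code{element},
#'   \code{mol} ("receptor"/"ligand") and \code{type}.
#' @slot topology the \linkS4class{ReceptorTopology}.
#' @slot metadata list (openness, seed, pose, ...).
#' @export
setClass("Conformation",
  representation(coords = "matrix", atoms = "data.frame",
                 topology = "ReceptorTopology", metadata = "list"),
  validity = function(object) {
    msg <- character()
    X <- object@coords
    if (ncol(X) != 3L) msg <- c(msg, "coords must have 3 columns")
    if (is.null(rownames(X)) || anyDuplicated(rownames(X)))
      msg <- c(msg, "coords need unique rownames")
    if (!identical(rownames(X), object@atoms$label))
      msg <- c(msg, "coords rownames must match atom table")
    topo <- object@topology
    need <- c(topo@ringAtoms, topo@pyrrolicAtoms, paste0("N.", topo@sites))
    if (!all(need %in% rownames(X)))
      msg <- c(msg, "missing required receptor atoms")
    if (!length(msg)) {
      ring <- X[topo@ringAtoms, , drop = FALSE]
      ctr <- colMeans(ring)
      sv <- svd(sweep(ring, 2, ctr))
      ## smallest singular value bounds the out-of-plane spread
      if (sv$d[3] / sqrt(nrow(ring)) > .RING_PLANARITY_TOL)
        msg <- c(msg, "phenyl ring atoms are not coplanar")
      if (min(dist(X)) <= .DIST_FLOOR)
        msg <- c(msg, sprintf("coincident atoms: a distance is below %.2f nm",
                              .DIST_FLOOR))
    }
    if (length(msg)) msg else TRUE
  })

#' EnsembleRecord: an ordered synthetic conformational ensemble
#'
#' Frames share one topology and atom layout; coordinates are stored as a
#' list of matrices against a template \linkS4class{Conformation}, with an
#' optional protonation state per frame.  Use \code{\link{getFrame}} to
#' materialise frame i as a full Conformation.
#'
#' @slot template a \linkS4class{Conformation} defining atoms and topology.
#' @slot coordsList list of coordinate matrices, one per frame.
#' @slot states list of protonation-state vectors (may be empty).
#' @slot frames strictly increasing integer frame indices.
#' @slot metadata list: seed, generator parameters, pH if applicable.
#' @export
setClass("EnsembleRecord",
  representation(template = "Conformation", coordsList = "list",
                 states = "list", frames = "integer", metadata = "list"),
  validity = function(object) {
    msg <- character()
    n <- length(object@coordsList)
    if (length(object@frames) != n)
      msg <- c(msg, "frames and coordsList lengths differ")
    if (n > 1 && any(diff(object@frames) <= 0))
      msg <- c(msg, "frame indices must be strictly increasing")
    if (length(object@states) && length(object@states) != n)
      msg <- c(msg, "states must be empty or one per frame")
    nr <- nrow(object@template@coords)
    ok <- vapply(object@coordsList, function(m)
      is.matrix(m) && nrow(m) == nr && ncol(m) == 3L, logical(1))
    if (!all(ok)) msg <- c(msg, "all frames must match the template layout")
    if (length(msg)) msg else TRUE
  })

#' TitrationModel: intrinsic pKa values plus pairwise interaction matrix
#'
#' The free energy (in pK units) of a protonation microstate s at a given pH
#' is \eqn{g(s) = \sum_i s_i (pH - pK_{int,i}) + \sum_{i<j} W_{ij} s_i s_j}.
#'
#' @slot pKint numeric(6) intrinsic pKa per site.
#' @slot W symmetric non-negative 6 x 6 interaction matrix, pK units, zero
#'   diagonal.
#' @slot topology the \linkS4class{ReceptorTopology}.
#' @slot degeneracy per-site tautomer multiplicity (default 1; reserved).
#' @export
setClass("TitrationModel",
  representation(pKint = "numeric", W = "matrix",
                 topology = "ReceptorTopology", degeneracy = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@topology@sites)
    if (length(object@pKint) != n) msg <- c(msg, "pKint length must match sites")
    if (!all(is.finite(object@pKint))) msg <- c(msg, "pKint must be finite")
    W <- object@W
    if (!all(dim(W) == c(n, n))) msg <- c(msg, "W must be n x n")
    else {
      if (max(abs(W - t(W))) > 1e-12) msg <- c(msg, "W must be symmetric")
      if (any(diag(W) != 0)) msg <- c(msg, "W must have zero diagonal")
      if (any(W < 0)) msg <- c(msg, "W must be non-negative (like charges repel)")
    }
    if (length(object@degeneracy) != n || any(object@degeneracy < 1))
      msg <- c(msg, "degeneracy must be >= 1 per site")
    if (length(msg)) msg else TRUE
  })

#' MicrostateDistribution: probabilities over protonation microstates
#'
#' Probabilities over the 2^n protonation microstates at one pH, from exact
#' enumeration or Monte Carlo frequencies.  States are named by their binary
#' occupation string in site order (e.g. "100110").
#'
#' @slot probabilities named numeric vector of length 2^n summing to 1.
#' @slot method "exact" or "mc".
#' @slot pH the pH of the calculation.
#' @slot nSamples MC sample count (NA for exact).
#' @slot topology the \linkS4class{ReceptorTopology}.
#' @export
setClass("MicrostateDistribution",
  representation(probabilities = "numeric", method = "character",
                 pH = "numeric", nSamples = "numeric",
                 topology = "ReceptorTopology"),
  validity = function(object) {
    msg <- character()
    p <- object@probabilities
    if (any(p < 0)) msg <- c(msg, "probabilities must be >= 0")
    if (abs(sum(p) - 1) > 1e-12) msg <- c(msg, "probabilities must sum to 1")
    if (is.null(names(p))) msg <- c(msg, "probabilities must be named by state")
    if (!object@method %in% c("exact", "mc")) msg <- c(msg, "method must be exact or mc")
    if (length(msg)) msg else TRUE
  })

#' TitrationCurve: occupancies against pH
#'
#' @slot curve data.frame: pH, total, total_se, gen1_percent, gen2_percent
#'   and one occupancy column per site.
#' @slot engine "exact" or "mc".
#' @slot metadata list (seed, steps, ...).
#' @export
setClass("TitrationCurve",
  representation(curve = "data.frame", engine = "character",
                 metadata = "list"),
  validity = function(object) {
    msg <- character()
    cv <- object@curve
    need <- c("pH", "total", "gen1_percent", "gen2_percent")
    if (!all(need %in% names(cv))) msg <- c(msg, "curve misses required columns")
    else {
      if (any(cv$total < -1e-9 | cv$total > 6 + 1e-9))
        msg <- c(msg, "total protonation must lie in [0, 6]")
      site_cols <- grep("^occ\\.", names(cv), value = TRUE)
      if (length(site_cols)) {
        occ <- as.matrix(cv[site_cols])
        if (any(occ < -1e-9 | occ > 1 + 1e-9))
          msg <- c(msg, "site occupancies must lie in [0, 1]")
        if (max(abs(rowSums(occ) - cv$total)) > 1e-6)
          msg <- c(msg, "total must equal the sum of site occupancies")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' LandscapeGrid: 2-D kernel density and derived free-energy surface
#'
#' Free energy is \eqn{\Delta G(x) = -kT \ln(P(x)/P_{max})} in kT units; the
#' minimum over the grid is exactly 0 and bins with zero density carry +Inf
#' (use \code{\link{cappedFreeEnergy}} for plotting).
#'
#' @slot x,y bin-centre coordinates.
#' @slot density probability density per bin (integrates to 1 on the grid).
#' @slot freeEnergy free energy per bin in kT units.
#' @slot bandwidth Gaussian kernel standard deviations used (per axis).
#' @slot temperature kelvin (for reporting kT in kJ/mol).
#' @export
setClass("LandscapeGrid",
  representation(x = "numeric", y = "numeric", density = "matrix",
                 freeEnergy = "matrix", bandwidth = "numeric",
                 temperature = "numeric"),
  validity = function(object) {
    msg <- character()
    D <- object@density
    if (!all(dim(D) == c(length(object@x), length(object@y))))
      msg <- c(msg, "density dimensions must match grid")
    if (any(D < 0)) msg <- c(msg, "density must be >= 0")
    dx <- mean(diff(object@x)); dy <- mean(diff(object@y))
    tot <- sum(D) * dx * dy
    if (abs(tot - 1) > 0.01)
      msg <- c(msg, sprintf("density must integrate to 1 within 1%% (got %.4f)", tot))
    fe <- object@freeEnergy[is.finite(object@freeEnergy)]
    if (length(fe) && abs(min(fe)) > 1e-12)
      msg <- c(msg, "free-energy minimum must be exactly 0")
    if (length(object@bandwidth) != 2L || any(object@bandwidth <= 0))
      msg <- c(msg, "bandwidth must be two positive values")
    if (length(msg)) msg else TRUE
  })

#' SeriesError: autocorrelation-corrected error of a time-series mean
#'
#' @slot mean,variance series mean and variance.
#' @slot inefficiency statistical inefficiency g >= 1.
#' @slot se corrected standard error sqrt(var * g / N).
#' @slot neff effective number of independent samples N / g.
#' @export
setClass("SeriesError",
  representation(mean = "numeric", variance = "numeric",
                 inefficiency = "numeric", se = "numeric", neff = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@inefficiency < 1) msg <- c(msg, "inefficiency must be >= 1")
    if (object@se < 0) msg <- c(msg, "se must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' HBondCriterion: geometric hydrogen-bond criterion
#'
#' A donor--acceptor pair is hydrogen bonded when the donor--acceptor
#' distance is at most \code{distanceCutoff} and the deviation of the
#' donor-H-acceptor angle from linearity is at most \code{angleCutoff}.
#' Defaults are the community-standard 0.35 nm / 30 degrees.
#'
#' @slot distanceCutoff donor--acceptor distance cutoff, nm.
#' @slot angleCutoff deviation-from-linearity cutoff, degrees (<= 90).
#' @export
setClass("HBondCriterion",
  representation(distanceCutoff = "numeric", angleCutoff = "numeric"),
  prototype(distanceCutoff = 0.35, angleCutoff = 30),
  validity = function(object) {
    msg <- character()
    if (object@distanceCutoff <= 0) msg <- c(msg, "distance cutoff must be > 0")
    if (object@angleCutoff <= 0 || object@angleCutoff > 90)
      msg <- c(msg, "angle cutoff must be in (0, 90] degrees")
    if (length(msg)) msg else TRUE
  })

#' RestraintSpec: piecewise flat/quadratic/linear distance restraint
#'
#' Flat (zero) up to \code{r0}, quadratic \eqn{k/2 (d - r0)^2} between
#' \code{r0} and \code{r1}, linear with matched value and slope above
#' \code{r1}.  Defaults: k = 100 kJ mol^-1 nm^-2, r0 = 1.0 nm, r1 = 1.2 nm.
#'
#' @slot k force constant, kJ mol^-1 nm^-2.
#' @slot r0 flat radius, nm.
#' @slot r1 quadratic-to-linear switch, nm.
#' @export
setClass("RestraintSpec",
  representation(k = "numeric", r0 = "numeric", r1 = "numeric"),
  prototype(k = 100, r0 = 1.0, r1 = 1.2),
  validity = function(object) {
    msg <- character()
    if (object@k <= 0) msg <- c(msg, "k must be > 0")
    if (!(object@r0 > 0 && object@r1 > object@r0))
      msg <- c(msg, "need 0 < r0 < r1")
    if (length(msg)) msg else TRUE
  })

#' @describeIn HBondCriterion-class constructor.
#' @param distanceCutoff,angleCutoff see slots.
#' @export
HBondCriterion <- function(distanceCutoff = 0.35, angleCutoff = 30) {
  new("HBondCriterion", distanceCutoff = distanceCutoff,
      angleCutoff = angleCutoff)
}

#' @describeIn RestraintSpec-class constructor.
#' @param k,r0,r1 see slots.
#' @export
RestraintSpec <- function(k = 100, r0 = 1.0, r1 = 1.2) {
  new("RestraintSpec", k = k, r0 = r0, r1 = r1)
}
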