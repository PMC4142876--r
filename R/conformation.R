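# Synthetic receptor geometry: a coarse bead model carrying only the atoms
# the analyses reference.  Distances are calibrated so that the closed state
# has Rg near 0.50 nm and the fully open state Rg above 0.65 nm, with the
# first-generation amines clustered near the core and the second-generation
# amines exposed at the arm tips.

.RING_RADIUS <- 0.139      # phenyl C-C bond length = hexagon circumradius, nm
.PYRROLIC_DIST <- 0.72     # pyrrolic N distance from ring centroid, nm
.GEN1_DIST <- 0.52         # first-generation amine N distance, nm
.GEN2_DIST_CLOSED <- 1.05  # second-generation amine N, closed arms, nm
.GEN2_DIST_OPEN <- 1.40    # second-generation amine N, open arms, nm
.ARM_ELEV_CLOSED <- 35     # arm elevation from the ring normal, degrees
.ARM_ELEV_OPEN <- 90
.ARM_TWIST <- 18           # chiral azimuthal twist of each arm, degrees
.NH_BOND <- 0.10           # polar N-H bond length, nm

## Unit arm direction vectors for the three arms at a given openness.
.armDirections <- function(openness) {
  alpha <- (.ARM_ELEV_CLOSED +
              openness * (.ARM_ELEV_OPEN - .ARM_ELEV_CLOSED)) * pi / 180
  t(vapply(0:2, function(k) {
    phi <- k * 2 * pi / 3 + .ARM_TWIST * pi / 180
    u <- c(cos(phi), sin(phi), 0)
    sin(alpha) * u + cos(alpha) * c(0, 0, 1)
  }, numeric(3)))
}

## Fast path used by the coupled loop: the 6 amine N coordinates only,
## ideal geometry (no noise), rows in topology site order (g1 x3, g2 x3).
.amineCoordsFast <- function(openness) {
  v <- .armDirections(openness)
  d2 <- .GEN2_DIST_CLOSED + openness * (.GEN2_DIST_OPEN - .GEN2_DIST_CLOSED)
  rbind(.GEN1_DIST * v, d2 * v)
}

.receptorAtomTable <- function(topology) {
  labels <- c(topology@ringAtoms,
              unlist(lapply(1:3, function(a)
                c(paste0("NP.a", a), paste0("HNP.a", a),
                  paste0("N.a", a, ".g1"), paste0("H.a", a, ".g1"),
                  paste0("N.a", a, ".g2"), paste0("H.a", a, ".g2")))))
  data.frame(label = labels,
             element = substr(labels, 1, 1),
             mol = "receptor",
             type = ifelse(grepl("^C", labels), "ring",
                    ifelse(grepl("^NP", labels), "pyrrolic",
                    ifelse(grepl("^HNP", labels), "pyrroleH",
                    ifelse(grepl("^N\\.", labels), "amine", "amineH")))),
             stringsAsFactors = FALSE)
}

## Classify arbitrary atom labels into the table layout (used when
## rebuilding a Conformation from coordinates, e.g. after file I/O).
.atomTableFromLabels <- function(labels) {
  type <- rep(NA_character_, length(labels))
  type[grepl("^C[1-6]$", labels)] <- "ring"
  type[grepl("^NP\\.a[1-3]$", labels)] <- "pyrrolic"
  type[grepl("^HNP\\.a[1-3]$", labels)] <- "pyrroleH"
  type[grepl("^N\\.a[1-3]\\.g[12]$", labels)] <- "amine"
  type[grepl("^H\\.a[1-3]\\.g[12]$", labels)] <- "amineH"
  type[grepl("^(SC[1-5]|SO5)$", labels)] <- "sugarRing"
  type[labels == "O1"] <- "glycosidicO"
  type[grepl("^O[2346]$", labels)] <- "hydroxylO"
  type[grepl("^HO[2346]$", labels)] <- "hydroxylH"
  type[grepl("^CT[1-8]$", labels)] <- "tail"
  if (anyNA(type))
    stop("unrecognised atom labels: ",
         paste(labels[is.na(type)], collapse = ", "))
  element <- ifelse(grepl("^H", labels), "H",
             ifelse(grepl("^(O|SO)", labels), "O",
             ifelse(grepl("^N", labels), "N", "C")))
  mol <- ifelse(type %in% c("sugarRing", "glycosidicO", "hydroxylO",
                            "hydroxylH", "tail"), "ligand", "receptor")
  data.frame(label = labels, element = element, mol = mol, type = type,
             stringsAsFactors = FALSE)
}

#' Rebuild a Conformation from labelled coordinates
#'
#' Atom roles are inferred from the canonical labels (ring \code{C1..C6},
#' pyrrolic \code{NP.a1..}, amines \code{N.a1.g1..} with hydrogens, ligand
#' \code{SC*/SO5/O*/HO*/CT*}), e.g. after reading an XYZ or PDB file written
#' by this package, or for hand-built test fixtures.
#'
#' @param coords numeric matrix (n x 3) in nm with canonical rownames.
#' @param metadata optional list stored with the conformation.
#' @return a \linkS4class{Conformation}.
#' @export
conformationFromCoords <- function(coords, metadata = list()) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, !is.null(rownames(coords)))
  new("Conformation", coords = coords,
      atoms = .atomTableFromLabels(rownames(coords)),
      topology = buildReceptorTopology(), metadata = metadata)
}

#' Generate a synthetic receptor conformation
#'
#' The single conformational order parameter is \code{openness}: the three
#' arms open radially and symmetrically from a folded arrangement
#' (openness 0, receptor Rg near 0.50 nm) to an extended one (openness 1,
#' Rg above 0.65 nm), with optional independent per-arm positional noise.
#' The geometry is chiral (fixed azimuthal arm twist); mirror images are
#' distinct conformations.
#'
#' @param openness real in [0, 1].
#' @param seed integer seed; the output is deterministic given
#'   (openness, seed, noise).
#' @param noise per-arm positional jitter, nm (applied to the pyrrolic and
#'   amine nitrogens; polar hydrogens follow their nitrogen).
#' @param topology a \linkS4class{ReceptorTopology}.
#' @return a \linkS4class{Conformation} with 24 receptor atoms (15 heavy,
#'   9 polar hydrogens).
#' @examples
#' conf <- generateConformation(0.5, seed = 7)
#' radiusOfGyration(conf)
#' @export
generateConformation <- function(openness, seed, noise = 0.02,
                                 topology = buildReceptorTopology()) {
  if (!is.numeric(openness) || length(openness) != 1 ||
      is.na(openness) || openness < 0 || openness > 1)
    stop("'openness' must be a single value in [0, 1]")
  stopifnot(is.numeric(seed), length(seed) == 1, noise >= 0)
  withSeed(seed, {
    ring <- t(vapply(0:5, function(i)
      .RING_RADIUS * c(cos(i * pi / 3), sin(i * pi / 3), 0), numeric(3)))
    v <- .armDirections(openness)
    d2 <- .GEN2_DIST_CLOSED +
      openness * (.GEN2_DIST_OPEN - .GEN2_DIST_CLOSED)
    zhat <- c(0, 0, 1)
    rows <- list()
    for (a in 1:3) {
      va <- v[a, ]
      jit <- function() if (noise > 0) rnorm(3, 0, noise) else numeric(3)
      np <- .PYRROLIC_DIST * va + jit()
      n1 <- .GEN1_DIST * va + jit()
      n2 <- d2 * va + jit()
      ## tangential N-H direction (chirality-consistent, never degenerate
      ## because the arm axis is never parallel to the ring normal)
      hdir <- function(p) {
        w <- c(zhat[2] * p[3] - zhat[3] * p[2],
               zhat[3] * p[1] - zhat[1] * p[3],
               zhat[1] * p[2] - zhat[2] * p[1])
        w / sqrt(sum(w^2))
      }
      rows[[a]] <- rbind(np, np + .NH_BOND * hdir(va),
                         n1, n1 + .NH_BOND * hdir(n1),
                         n2, n2 + .NH_BOND * hdir(n2))
    }
    atoms <- .receptorAtomTable(topology)
    X <- rbind(ring, do.call(rbind, rows))
    rownames(X) <- atoms$label
    new("Conformation", coords = X, atoms = atoms, topology = topology,
        metadata = list(openness = openness, seed = seed, noise = noise))
  })
}

#' Generate a synthetic conformational ensemble
#'
#' Frames are drawn with per-frame openness from the stated distribution;
#' a desk-scale stand-in for trajectory sampling.
#'
#' @param nFrames number of frames (>= 1).
#' @param opennessDistribution \code{"uniform"} (uniform on [0, 1]), a
#'   single numeric (point mass), or a function \code{n -> numeric(n)}.
#' @param seed integer master seed; frame seeds are derived from it.
#' @param noise per-arm positional jitter passed to
#'   \code{\link{generateConformation}}.
#' @return an \linkS4class{EnsembleRecord}.
#' @examples
#' ens <- generateEnsemble(10, 0.5, seed = 3)
#' nFrames(ens)
#' @export
generateEnsemble <- function(nFrames, opennessDistribution = "uniform",
                             seed, noise = 0.02) {
  if (!is.numeric(nFrames) || nFrames < 1)
    stop("'nFrames' must be >= 1")
  nFrames <- as.integer(nFrames)
  stopifnot(!missing(seed))
  withSeed(seed, {
    openness <- if (is.function(opennessDistribution)) {
      opennessDistribution(nFrames)
    } else if (is.numeric(opennessDistribution)) {
      rep(opennessDistribution[1], nFrames)
    } else if (identical(opennessDistribution, "uniform")) {
      runif(nFrames)
    } else stop("unknown openness distribution")
    if (any(openness < 0 | openness > 1))
      stop("openness values must lie in [0, 1]")
    frameSeeds <- sample.int(.Machine$integer.max - 1L, nFrames)
    confs <- lapply(seq_len(nFrames), function(i)
      generateConformation(openness[i], frameSeeds[i], noise = noise))
    new("EnsembleRecord",
        template = confs[[1]],
        coordsList = lapply(confs, function(cf) cf@coords),
        states = list(),
        frames = seq_len(nFrames),
        metadata = list(seed = seed, noise = noise,
                        openness = openness,
                        distribution = if (is.function(opennessDistribution))
                          "function" else opennessDistribution))
  })
}
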