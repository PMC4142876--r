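# Mannoside mimic: a coarse octyl alpha-D-mannoside with a pyranose-like
# six-atom ring (5 C + ring O), four hydroxyl O-H groups, a glycosidic O and
# an eight-carbon tail.  Three pose modes echo the binding modes seen in the
# two solvent regimes: "head" (sugar head group toward the arms, hydrogen
# bond rich), "tail" (octyl tail stacked over the phenyl ring, hydrophobic)
# and "loose" (no specific contact).

.SUGAR_RING_RADIUS <- 0.145
.LIGAND_CONTACT_FLOOR <- 0.1   # receptor-ligand steric floor, nm
.PLACE_RETRIES <- 100
.HB_SNAP_DIST <- 0.29          # snapped O...N donor-acceptor distance, nm
.HB_SNAP_MAX <- 0.6            # max displacement allowed when snapping, nm
.OH_BOND <- 0.10

.ligandAtomLabels <- function() {
  c(paste0("SC", 1:5), "SO5", "O1",
    "O2", "HO2", "O3", "HO3", "O4", "HO4", "O6", "HO6",
    paste0("CT", 1:8))
}

## Build ligand coordinates for one pose, in the receptor frame (phenyl
## centroid at origin, ring normal = +z, arms above).  Returns a labelled
## coordinate matrix; may use the RNG (caller seeds it).
.buildLigand <- function(conf, pose, maxRingSeparation, jitter = 0) {
  topo <- conf@topology
  acceptorN <- coords(conf, paste0("N.", topo@sites))
  unit <- function(v) v / sqrt(sum(v^2))

  hexagon <- function(centre, azimuth = 0) {
    t(vapply(0:5, function(i) {
      phi <- azimuth + i * pi / 3
      centre + .SUGAR_RING_RADIUS * c(cos(phi), sin(phi), 0)
    }, numeric(3)))
  }

  if (pose == "head") {
    h <- min(0.75, maxRingSeparation)
    centre <- c(0, 0, h) + jitter * rnorm(3)
    ring <- hexagon(centre)
    ## nominal hydroxyl positions: outward from ring vertices 2..5
    nominal <- t(vapply(1:4, function(k) {
      vtx <- ring[k + 1, ]
      vtx + 0.13 * unit(c(vtx[1] - centre[1], vtx[2] - centre[2], 0))
    }, numeric(3)))
    ## snap each hydroxyl toward its nearest free amine nitrogen, capped
    used <- rep(FALSE, nrow(acceptorN))
    O <- nominal; H <- nominal
    for (k in 1:4) {
      d <- sqrt(rowSums(sweep(acceptorN, 2, nominal[k, ])^2))
      d[used] <- Inf
      j <- which.min(d)
      if (d[j] <= .HB_SNAP_MAX) {
        used[j] <- TRUE
        dir <- unit(nominal[k, ] - acceptorN[j, ])
        O[k, ] <- acceptorN[j, ] + .HB_SNAP_DIST * dir
        H[k, ] <- O[k, ] + .OH_BOND * unit(acceptorN[j, ] - O[k, ])
      } else {
        H[k, ] <- O[k, ] + .OH_BOND * unit(O[k, ] - centre)
      }
    }
    O1 <- ring[1, ] + 0.13 * c(0, 0, 1)
    tailDir <- c(0, 0, 1)
    tailStart <- O1 + 0.13 * tailDir
    tail <- t(vapply(0:7, function(i)
      tailStart + i * 0.127 * tailDir +
        c(0.04 * (i %% 2), 0, 0), numeric(3)))
  } else if (pose == "tail") {
    ## terminal tail carbons stacked over the phenyl ring, sugar to the
    ## side, the whole construct rotated into the gap between arms 1 and 2
    ## (the arms sit at azimuths 18, 138 and 258 degrees)
    s <- min(1, maxRingSeparation / 1.05)
    end <- c(0.05, 0, 0.32) + jitter * rnorm(3)
    start <- s * c(0.44, 0.05, 0.50)
    tail <- t(vapply(0:7, function(i) {
      f <- i / 7
      start + f * (end - start) + c(0, 0.045 * (i %% 2 - 0.5), 0)
    }, numeric(3)))
    O1 <- start + c(0.09, 0, 0.10)
    centre <- O1 + s * c(0.14, 0, 0.10)
    ring <- hexagon(centre, azimuth = pi / 6)
    O <- t(vapply(1:4, function(k) {
      vtx <- ring[k + 1, ]
      vtx + 0.13 * unit(c(vtx[1] - centre[1], vtx[2] - centre[2], 0.6))
    }, numeric(3)))
    H <- O + 0.1 * t(vapply(1:4, function(k)
      unit(c(O[k, 1] - centre[1], O[k, 2] - centre[2], 0.8)), numeric(3)))
    az <- 78 * pi / 180 + if (jitter > 0) rnorm(1, 0, 0.4) else 0
    Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3)
    rot <- function(M) M %*% t(Rz)
    ring <- rot(ring); O <- rot(O); H <- rot(H); tail <- rot(tail)
    O1 <- as.numeric(O1 %*% t(Rz))
  } else { # loose
    theta <- runif(1, 0, 70) * pi / 180
    phi <- runif(1, 0, 2 * pi)
    lo <- min(0.6, 0.8 * maxRingSeparation)
    u <- runif(1, lo, max(lo + 0.01, min(0.95, maxRingSeparation)))
    centre <- u * c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    ring <- hexagon(centre, azimuth = runif(1, 0, 2 * pi))
    away <- unit(centre + c(0, 0, 1e-6))
    O <- t(vapply(1:4, function(k) {
      vtx <- ring[k + 1, ]
      vtx + 0.13 * unit(vtx - centre + 0.05 * away)
    }, numeric(3)))
    H <- O + 0.1 * t(vapply(1:4, function(k) unit(O[k, ] - centre),
                            numeric(3)))
    O1 <- ring[1, ] + 0.13 * away
    tail <- t(vapply(0:7, function(i)
      O1 + (0.13 + i * 0.127) * away +
        c(0.04 * (i %% 2), -0.04 * (i %% 2), 0), numeric(3)))
  }

  L <- rbind(ring, O1, O[1, ], H[1, ], O[2, ], H[2, ],
             O[3, ], H[3, ], O[4, ], H[4, ], tail)
  rownames(L) <- .ligandAtomLabels()
  L
}

#' Place the mannoside mimic next to a receptor conformation
#'
#' Adds a coarse octyl mannoside (six-atom sugar ring, four hydroxyl O-H
#' groups, glycosidic oxygen, eight tail carbons) with its sugar-ring
#' centroid within \code{maxRingSeparation} of the phenyl-ring centroid.
#' Placement is deterministic given \code{poseSeed}.  In the \code{"head"}
#' pose the hydroxyl groups are directed at nearby amine nitrogens (hydrogen
#' bond rich); in the \code{"tail"} pose the terminal tail carbons stack
#' over the phenyl ring; \code{"loose"} places the ligand at a random
#' orientation inside the restraint sphere.
#'
#' @param conf a receptor \linkS4class{Conformation} (ligand-free).
#' @param poseSeed integer seed controlling the pose.
#' @param maxRingSeparation maximum sugar-ring to phenyl-ring centroid
#'   separation, nm (default 1.0, the flat radius of the study restraint).
#' @param pose "head", "tail" or "loose".
#' @return a \linkS4class{Conformation} including the ligand block.
#' @examples
#' conf <- generateConformation(0.2, seed = 4)
#' bound <- placeMannoside(conf, poseSeed = 11)
#' hasLigand(bound)
#' @export
placeMannoside <- function(conf, poseSeed, maxRingSeparation = 1.0,
                           pose = c("head", "tail", "loose")) {
  stopifnot(is(conf, "Conformation"), maxRingSeparation > 0)
  pose <- match.arg(pose)
  if (hasLigand(conf)) stop("conformation already carries a ligand")
  withSeed(poseSeed, {
    X <- conf@coords
    for (try in seq_len(.PLACE_RETRIES)) {
      L <- .buildLigand(conf, pose, maxRingSeparation,
                        jitter = 0.02 * (try - 1))
      ## steric floor between receptor and ligand atoms
      dmin <- min(vapply(seq_len(nrow(L)), function(i)
        min(sqrt(rowSums(sweep(X, 2, L[i, ])^2))), numeric(1)))
      if (dmin > .LIGAND_CONTACT_FLOOR && min(dist(L)) > .DIST_FLOOR) {
        atoms <- rbind(conf@atoms, .atomTableFromLabels(rownames(L)))
        out <- new("Conformation", coords = rbind(X, L), atoms = atoms,
                   topology = conf@topology,
                   metadata = c(conf@metadata,
                                list(pose = pose, poseSeed = poseSeed,
                                     maxRingSeparation = maxRingSeparation)))
        return(out)
      }
    }
    stop("could not place the mannoside without steric overlap after ",
         .PLACE_RETRIES, " retries")
  })
}
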