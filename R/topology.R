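# Canonical receptor topology and the arm permutation group.

#' Build the canonical receptor topology
#'
#' Three identical arms on a central phenyl ring; each arm carries one
#' pyrrolic nitrogen and two titratable secondary amines, the
#' first-generation amine near the core and the second-generation amine at
#' the arm tip.  Site order is generation-major:
#' \code{a1.g1, a2.g1, a3.g1, a1.g2, a2.g2, a3.g2}.
#'
#' @return a \linkS4class{ReceptorTopology}.
#' @examples
#' topo <- buildReceptorTopology()
#' armOf(topo)
#' generationOf(topo)
#' @export
buildReceptorTopology <- function() {
  sites <- c("a1.g1", "a2.g1", "a3.g1", "a1.g2", "a2.g2", "a3.g2")
  new("ReceptorTopology",
      nArms = 3L,
      sites = sites,
      arm = c(1L, 2L, 3L, 1L, 2L, 3L),
      generation = c(1L, 1L, 1L, 2L, 2L, 2L),
      pyrrolicAtoms = paste0("NP.a", 1:3),
      ringAtoms = paste0("C", 1:6))
}

#' Arm permutations and their action on sites
#'
#' The symmetry group of the tripodal receptor acting on arm labels.  The
#' \code{"cyclic"} group contains the three rotations (the receptor is
#' chiral, so reflections are excluded by default for RMSD purposes); the
#' \code{"full"} group contains all six permutations of the arms and is the
#' one under which microstate classes are merged.
#'
#' @param topology a \linkS4class{ReceptorTopology}.
#' @param group "cyclic" (3 rotations) or "full" (all 6 permutations).
#' @return list of integer site-index permutations \code{p}; permuted state
#'   \code{s[p]} relabels arm \code{a} to carry what arm \code{p(a)} had.
#' @examples
#' perms <- armPermutations(buildReceptorTopology(), "full")
#' length(perms)  # 6
#' @export
armPermutations <- function(topology, group = c("cyclic", "full")) {
  group <- match.arg(group)
  armPerms <- list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
  if (group == "full")
    armPerms <- c(armPerms,
                  list(c(1L, 3L, 2L), c(3L, 2L, 1L), c(2L, 1L, 3L)))
  lapply(armPerms, function(p) {
    ## site index permutation: for each site, the site of the same
    ## generation on arm p[arm]
    vapply(seq_along(topology@sites), function(i) {
      a <- topology@arm[i]; g <- topology@generation[i]
      which(topology@arm == p[a] & topology@generation == g)
    }, integer(1))
  })
}

## Map an arm permutation to the induced permutation of atom labels
## (ring, pyrrolic, amine N and polar H), used by symmetryRMSD.
.atomPermutation <- function(topology, armPerm, labels) {
  ## arm k attaches at ring atom 2k-1; rotations move the hexagon by two
  ## positions, swaps act as reflections of the hexagon through the axis of
  ## the fixed arm.  Represent ring position i by angle (i-1)*60 deg.
  ringMap <- integer(6)
  ang <- (0:5) * 60
  armAng <- (0:2) * 120                     # attachment angles of arms 1..3
  if (identical(sort(armPerm), 1:3)) {
    fixed <- which(armPerm == seq_len(3))
    isRotation <- length(fixed) %in% c(0L, 3L)
    if (isRotation) {
      shift <- armAng[armPerm[1]] - armAng[1]
      newAng <- (ang + shift) %% 360
    } else {
      axis <- armAng[fixed[1]]
      newAng <- (2 * axis - ang) %% 360
    }
    ringMap <- match(round(newAng), round(ang))
  }
  out <- labels
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (grepl("^C[1-6]$", lab)) {
      out[i] <- paste0("C", ringMap[as.integer(sub("C", "", lab))])
    } else if (grepl("\\.a[1-3]", lab)) {
      a <- as.integer(sub(".*\\.a([1-3]).*", "\\1", lab))
      out[i] <- sub(paste0("\\.a", a), paste0(".a", armPerm[a]), lab)
    }
  }
  out
}
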