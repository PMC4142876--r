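# Structural descriptors: radius of gyration, symmetry-corrected RMSD and
# the arm-position map in the phenyl-ring frame.

## Default atom selection for receptor descriptors: the 15 heavy atoms
## (ring, pyrrolic N, amine N); polar hydrogens are bookkeeping for the
## hydrogen-bond analysis, not structure.
.receptorHeavySelection <- function(conf) {
  conf@atoms$label[conf@atoms$mol == "receptor" &
                     conf@atoms$type %in% c("ring", "pyrrolic", "amine")]
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the selected atoms from their
#' centre of mass,
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{cm}|^2 / \sum_i m_i}}.
#' Default selection: all receptor heavy atoms with unit masses.
#'
#' @param conf a \linkS4class{Conformation}.
#' @param selection atom labels (default: receptor heavy atoms).
#' @param masses per-atom masses (default: unit).
#' @return Rg in nm.
#' @examples
#' radiusOfGyration(generateConformation(0, seed = 1, noise = 0))  # ~0.50
#' @export
radiusOfGyration <- function(conf, selection = NULL, masses = NULL) {
  stopifnot(is(conf, "Conformation"))
  if (is.null(selection)) selection <- .receptorHeavySelection(conf)
  if (!length(selection)) stop("empty atom selection")
  X <- coords(conf, selection)
  if (is.null(masses)) masses <- rep(1, nrow(X))
  stopifnot(length(masses) == nrow(X), all(masses > 0))
  cm <- colSums(X * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(X, 2, cm)^2)) / sum(masses))
}

## Kabsch optimal superposition: rotation (proper, no reflection) and
## translation minimising the RMSD of X onto Y.  Returns the minimal RMSD.
.kabschRMSD <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Xr <- Xc %*% t(R)
  sqrt(mean(rowSums((Xr - Yc)^2)))
}

#' Symmetry-corrected RMSD between two conformations
#'
#' For each allowed arm relabelling, the conformations are optimally
#' superposed by a least-squares rigid-body fit (proper rotations only) and
#' the minimum RMSD over relabellings is returned.  The default group is
#' the three cyclic arm rotations: the receptor is chiral, so reflections
#' are excluded; the full six-element permutation group is available for
#' comparison with the microstate classification convention.
#'
#' @param conf,ref two \linkS4class{Conformation}s sharing the topology.
#' @param group "cyclic" (default) or "full".
#' @param selection atom labels used in the fit (default: receptor heavy
#'   atoms; must exist in both conformations).
#' @return minimal RMSD in nm.
#' @examples
#' a <- generateConformation(0.3, seed = 1)
#' symmetryRMSD(a, a)  # 0
#' @export
symmetryRMSD <- function(conf, ref, group = c("cyclic", "full"),
                         selection = NULL) {
  stopifnot(is(conf, "Conformation"), is(ref, "Conformation"))
  group <- match.arg(group)
  if (is.null(selection)) selection <- .receptorHeavySelection(ref)
  if (!all(selection %in% rownames(conf@coords)) ||
      !all(selection %in% rownames(ref@coords)))
    stop("selection atoms missing from one of the conformations")
  Y <- coords(ref, selection)
  topo <- ref@topology
  armPerms <- if (group == "cyclic") {
    list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
  } else {
    list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L),
         c(1L, 3L, 2L), c(3L, 2L, 1L), c(2L, 1L, 3L))
  }
  vapply(armPerms, function(p) {
    permLabels <- .atomPermutation(topo, p, selection)
    X <- coords(conf, permLabels)
    .kabschRMSD(X, Y)
  }, numeric(1)) |> min()
}

## Orthonormal local frame of the phenyl ring: origin at the ring centroid,
## z along the ring normal (right-handed from the first two ring atoms),
## x along the in-plane projection of ring atom 1.  Covariant with rigid
## motions, so descriptors expressed in it are rigid-motion invariant.
.ringFrame <- function(conf) {
  ring <- coords(conf, conf@topology@ringAtoms)
  ctr <- colMeans(ring)
  a1 <- ring[1, ] - ctr
  a2 <- ring[2, ] - ctr
  z <- c(a1[2] * a2[3] - a1[3] * a2[2],
         a1[3] * a2[1] - a1[1] * a2[3],
         a1[1] * a2[2] - a1[2] * a2[1])
  nz <- sqrt(sum(z^2))
  if (nz < 1e-8) stop("degenerate (collinear) ring atoms: no frame")
  z <- z / nz
  x <- a1 - sum(a1 * z) * z
  nx <- sqrt(sum(x^2))
  if (nx < 1e-8) stop("degenerate ring geometry: no in-plane axis")
  x <- x / nx
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  list(origin = ctr, basis = cbind(x, y, z))
}

#' Pyrrolic nitrogen positions in the phenyl-ring frame
#'
#' Expresses the three pyrrolic nitrogens in the local frame defined by the
#' ring centroid (origin), the ring normal (z) and a deterministic in-plane
#' axis (x along ring atom 1).  The output is invariant under global rigid
#' motion of the conformation and maps how far the arms reach out and up.
#'
#' @param conf a \linkS4class{Conformation}.
#' @return 3 x 3 matrix (one row per arm, columns x, y, z in nm).
#' @examples
#' armPositions(generateConformation(0.8, seed = 2))
#' @export
armPositions <- function(conf) {
  stopifnot(is(conf, "Conformation"))
  fr <- .ringFrame(conf)
  P <- coords(conf, conf@topology@pyrrolicAtoms)
  out <- sweep(P, 2, fr$origin) %*% fr$basis
  colnames(out) <- c("x", "y", "z")
  out
}
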