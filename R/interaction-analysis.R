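# Receptor/mannoside interaction observables: geometric hydrogen bonds,
# tail-ring distance and the piecewise distance-restraint potential.

## Acceptor atom types (restricted to N/O elements; pyrrole N is a donor
## but a poor acceptor and is excluded).
.ACCEPTOR_TYPES <- c("amine", "hydroxylO", "glycosidicO", "sugarRing")

## Donor table: one row per declared donor heavy atom (amine N, pyrrolic N,
## hydroxyl O) with its expected hydrogen label.  The label conventions pair
## N.<site> with H.<site>, NP.a<k> with HNP.a<k> and O<j> with HO<j>; a
## declared donor whose hydrogen is absent is an input error, caught by the
## caller.
.donorTable <- function(conf) {
  at <- conf@atoms
  heavies <- at[at$type %in% c("amine", "pyrrolic", "hydroxylO"), ]
  hydrogen <- vapply(heavies$label, function(d) {
    if (startsWith(d, "NP.")) sub("^NP", "HNP", d)
    else if (startsWith(d, "N.")) sub("^N\\.", "H.", d)
    else sub("^O", "HO", d)
  }, character(1))
  data.frame(donor = heavies$label, hydrogen = hydrogen, mol = heavies$mol,
             stringsAsFactors = FALSE)
}

.acceptorTable <- function(conf) {
  at <- conf@atoms
  acc <- at[(at$type %in% .ACCEPTOR_TYPES) & at$element %in% c("N", "O"), ]
  data.frame(acceptor = acc$label, mol = acc$mol, stringsAsFactors = FALSE)
}

#' Detect intermolecular hydrogen bonds
#'
#' A bond is counted when the donor--acceptor distance is at most the
#' distance cutoff and the deviation of the donor-H-acceptor angle from
#' linearity is at most the angle cutoff; only receptor-ligand pairs are
#' considered and each donor-H is counted at most once per acceptor.
#' Receptor donors are the amine and pyrrole N-H groups; ligand donors are
#' the four hydroxyl O-H groups; acceptors are the amine nitrogens and the
#' hydroxyl, ring and glycosidic oxygens.
#'
#' @param conf a \linkS4class{Conformation} carrying the ligand.
#' @param criterion an \linkS4class{HBondCriterion}.
#' @return data.frame with columns \code{donor}, \code{hydrogen},
#'   \code{acceptor}, \code{distance}, \code{deviation}; the count is
#'   \code{nrow()} of the result.
#' @examples
#' conf <- placeMannoside(generateConformation(0.1, seed = 2), poseSeed = 5)
#' nrow(detectHBonds(conf))
#' @export
detectHBonds <- function(conf, criterion = HBondCriterion()) {
  stopifnot(is(conf, "Conformation"), is(criterion, "HBondCriterion"))
  if (!hasLigand(conf)) stop("conformation carries no ligand")
  don <- .donorTable(conf)
  acc <- .acceptorTable(conf)
  miss <- setdiff(don$donor, rownames(conf@coords))
  if (length(miss))
    stop("missing donor heavy atoms: ", paste(miss, collapse = ", "))
  missH <- setdiff(don$hydrogen, rownames(conf@coords))
  if (length(missH))
    stop("missing hydrogen coordinates for declared donors: ",
         paste(missH, collapse = ", "))
  X <- conf@coords
  hits <- list()
  for (i in seq_len(nrow(don))) {
    aa <- acc[acc$mol != don$mol[i], , drop = FALSE]
    if (!nrow(aa)) next
    D <- X[don$donor[i], ]; H <- X[don$hydrogen[i], ]
    A <- X[aa$acceptor, , drop = FALSE]
    dDA <- sqrt(rowSums(sweep(A, 2, D)^2))
    ok <- dDA <= criterion@distanceCutoff
    if (!any(ok)) next
    ## deviation from linearity of D-H-A at the hydrogen
    hd <- D - H; hd <- hd / sqrt(sum(hd^2))
    ha <- sweep(A[ok, , drop = FALSE], 2, H)
    ha <- ha / sqrt(rowSums(ha^2))
    cosang <- pmin(1, pmax(-1, as.numeric(ha %*% hd)))
    dev <- 180 - acos(cosang) * 180 / pi
    sel <- dev <= criterion@angleCutoff
    if (any(sel)) {
      hits[[length(hits) + 1L]] <- data.frame(
        donor = don$donor[i], hydrogen = don$hydrogen[i],
        acceptor = aa$acceptor[ok][sel],
        distance = dDA[ok][sel], deviation = dev[sel],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(donor = character(), hydrogen = character(),
                      acceptor = character(), distance = numeric(),
                      deviation = numeric(), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, hits))
}

#' Tail-ring distance
#'
#' Euclidean distance between the unit-mass centroid of the four terminal
#' tail carbons (atoms 5-8 of the octyl chain) and the centroid of the six
#' phenyl ring atoms; the hydrophobic stacking coordinate.
#'
#' @param conf a \linkS4class{Conformation} carrying the ligand.
#' @return distance in nm.
#' @export
tailRingDistance <- function(conf) {
  stopifnot(is(conf, "Conformation"))
  if (!hasLigand(conf)) stop("conformation carries no ligand")
  tail4 <- paste0("CT", 5:8)
  if (!all(tail4 %in% rownames(conf@coords)))
    stop("ligand tail carbons CT5..CT8 missing")
  ctTail <- colMeans(coords(conf, tail4))
  ctRing <- colMeans(coords(conf, conf@topology@ringAtoms))
  sqrt(sum((ctTail - ctRing)^2))
}

#' Single-distance restraint potential
#'
#' The piecewise penalty applied to one inter-ring atom-pair distance:
#' zero up to \code{r0}, quadratic \eqn{k/2 (d - r0)^2} between \code{r0}
#' and \code{r1}, linear above \code{r1} with continuous value and first
#' derivative.
#'
#' @param d distance(s) in nm.
#' @param spec a \linkS4class{RestraintSpec}.
#' @return energy in kJ/mol, vectorised over \code{d}.
#' @examples
#' restraintPotential(c(0.9, 1.2, 1.4), RestraintSpec())  # 0, 2, 6
#' @export
restraintPotential <- function(d, spec = RestraintSpec()) {
  stopifnot(is(spec, "RestraintSpec"), all(d >= 0))
  k <- spec@k; r0 <- spec@r0; r1 <- spec@r1
  e <- numeric(length(d))
  mid <- d > r0 & d <= r1
  e[mid] <- 0.5 * k * (d[mid] - r0)^2
  hi <- d > r1
  e[hi] <- 0.5 * k * (r1 - r0)^2 + k * (r1 - r0) * (d[hi] - r1)
  e
}

#' Piecewise ring-ring distance-restraint energy
#'
#' Restraint keeping the mannoside's sugar ring near the receptor's phenyl
#' ring: for each ring-atom pair distance d, the penalty is zero up to
#' \code{r0}, quadratic \eqn{k/2 (d - r0)^2} between \code{r0} and
#' \code{r1}, and linear above \code{r1} with continuous value and slope.
#' The default sums over all 36 pairs of the two six-atom rings; the
#' \code{"min"} variant penalises only the closest pair (the two readings
#' of a restraint on "the distance between the rings").
#'
#' @param conf a \linkS4class{Conformation} with both rings present.
#' @param spec a \linkS4class{RestraintSpec} (default 100 kJ/mol/nm^2,
#'   r0 = 1.0 nm, r1 = 1.2 nm).
#' @param variant "sum" (default) or "min".
#' @return energy in kJ/mol; zero when every pair (or the closest pair,
#'   for \code{"min"}) is within \code{r0}.
#' @export
restraintEnergy <- function(conf, spec = RestraintSpec(),
                            variant = c("sum", "min")) {
  stopifnot(is(conf, "Conformation"), is(spec, "RestraintSpec"))
  variant <- match.arg(variant)
  if (!hasLigand(conf)) stop("conformation carries no ligand")
  sugar <- c(paste0("SC", 1:5), "SO5")
  if (!all(sugar %in% rownames(conf@coords)))
    stop("sugar ring atoms missing")
  A <- coords(conf, conf@topology@ringAtoms)
  B <- coords(conf, sugar)
  d2 <- pmax(0, outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B))
  d <- as.numeric(sqrt(d2))
  if (variant == "min") restraintPotential(min(d), spec)
  else sum(restraintPotential(d, spec))
}

#' Interaction histograms over an ensemble
#'
#' Per-frame hydrogen-bond counts and tail-ring distances, binned with
#' autocorrelation-corrected errors.
#'
#' @param ensemble an \linkS4class{EnsembleRecord} whose frames carry the
#'   ligand.
#' @param criterion an \linkS4class{HBondCriterion}.
#' @param spec a \linkS4class{RestraintSpec} (restraint energies are
#'   reported per frame).
#' @param distBreaks bin specification for the distance histogram.
#' @return list: \code{perFrame} (frame, hbond_count, tail_ring_distance,
#'   restraint_energy), \code{hbondHistogram} (one bin per count),
#'   \code{distanceHistogram}.
#' @export
interactionHistograms <- function(ensemble, criterion = HBondCriterion(),
                                  spec = RestraintSpec(), distBreaks = 30) {
  stopifnot(is(ensemble, "EnsembleRecord"))
  n <- nFrames(ensemble)
  per <- data.frame(frame = ensemble@frames,
                    hbond_count = integer(n),
                    tail_ring_distance = numeric(n),
                    restraint_energy = numeric(n))
  for (i in seq_len(n)) {
    cf <- getFrame(ensemble, i)
    per$hbond_count[i] <- nrow(detectHBonds(cf, criterion))
    per$tail_ring_distance[i] <- tailRingDistance(cf)
    per$restraint_energy[i] <- restraintEnergy(cf, spec)
  }
  maxCount <- max(per$hbond_count)
  hb <- histogramWithErrors(per$hbond_count,
                            breaks = seq(-0.5, maxCount + 0.5, by = 1))
  dist <- histogramWithErrors(per$tail_ring_distance, breaks = distBreaks)
  list(perFrame = per, hbondHistogram = hb, distanceHistogram = dist)
}
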