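# Symmetry classes of protonation microstates.
#
# Microstates are grouped by the number of bound protons n and merged into
# equivalence classes under the full arm-permutation group (all six
# permutations of the three identical arms, preserving generation labels).
# The class counts per n = 0..6 are (1, 2, 4, 6, 4, 2, 1); the printed class
# diagram of the receptor shows the six classes at n = 3.

## Canonical orbit representative: the lexicographically smallest occupation
## string over all images of the state under the group.
.orbitKey <- function(state, perms) {
  keys <- vapply(perms, function(p) paste(state[p], collapse = ""),
                 character(1))
  min(keys)
}

## Human-readable class descriptor built from the multiset of per-arm
## occupation patterns (each arm is 00, g1, g2 or g1+g2).
.classDescriptor <- function(state, topology) {
  armPat <- vapply(1:3, function(a) {
    i1 <- which(topology@arm == a & topology@generation == 1L)
    i2 <- which(topology@arm == a & topology@generation == 2L)
    paste0(state[i1], state[i2])
  }, character(1))
  n1 <- sum(state[topology@generation == 1L])
  n2 <- sum(state[topology@generation == 2L])
  both <- sum(armPat == "11")
  desc <- sprintf("%dxgen1+%dxgen2", n1, n2)
  if (n1 > 0 && n2 > 0)
    desc <- paste0(desc, sprintf(", %d arm(s) doubly protonated", both))
  desc
}

#' Classify microstates into arm-symmetry classes
#'
#' Groups the 64 microstates by the number of bound protons n, then merges
#' them into equivalence classes under the full arm-permutation group.
#' Class populations are conditional on n (they sum to 1 within each n that
#' carries probability mass).
#'
#' @param dist a \linkS4class{MicrostateDistribution}.
#' @param topology a \linkS4class{ReceptorTopology} (defaults to the
#'   distribution's own).
#' @return data.frame with columns \code{n}, \code{class} (descriptor),
#'   \code{representative} (canonical occupation string), \code{nStates}
#'   (orbit size), \code{probability} (unconditional) and
#'   \code{population} (conditional on n).
#' @examples
#' d <- enumerateEquilibrium(plateauCalibrationModel(), pH = 6)
#' cls <- classifyMicrostates(d)
#' table(cls$n)  # 1 2 4 6 4 2 1 classes for n = 0..6
#' @export
classifyMicrostates <- function(dist, topology = dist@topology) {
  stopifnot(is(dist, "MicrostateDistribution"))
  p <- dist@probabilities
  S <- .stateMatrix(length(topology@sites))
  perms <- armPermutations(topology, "full")
  keys <- apply(S, 1, .orbitKey, perms = perms)
  n <- rowSums(S)
  df <- data.frame(key = keys, n = n, probability = p,
                   stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(df, df$key), function(d) {
    data.frame(n = d$n[1], representative = d$key[1],
               nStates = nrow(d), probability = sum(d$probability),
               stringsAsFactors = FALSE)
  }))
  agg$class <- vapply(agg$representative, function(k)
    .classDescriptor(as.integer(strsplit(k, "")[[1]]), topology),
    character(1))
  pn <- tapply(agg$probability, agg$n, sum)
  agg$population <- ifelse(pn[as.character(agg$n)] > 0,
                           agg$probability / pn[as.character(agg$n)], NA)
  agg <- agg[order(agg$n, -agg$probability), ]
  rownames(agg) <- NULL
  agg[, c("n", "class", "representative", "nStates", "probability",
          "population")]
}
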