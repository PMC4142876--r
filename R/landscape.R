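# Kernel-density free-energy landscapes over 2-D structural coordinates.

#' Free-energy landscape from 2-D samples
#'
#' Gaussian-kernel density estimate of the sample distribution on a regular
#' grid, converted to a free-energy surface
#' \deqn{\Delta G(x) = -kT \ln(P(x) / P_{max}),}
#' reported in kT units; the minimum over the grid is exactly 0 at the
#' density mode and bins with zero density carry +Inf (see
#' \code{\link{cappedFreeEnergy}}).
#'
#' The default bandwidth is Scott's rule per axis
#' (\eqn{h_i = \sigma_i n^{-1/6}}); the grid is padded beyond the sample
#' range by 5\% of the range or three bandwidths, whichever is larger, so
#' the density integrates to 1 on the grid.
#'
#' @param samples two-column matrix or data.frame of (x, y) samples
#'   (at least 2 rows).
#' @param gridSize number of bins per axis (default c(100, 100)).
#' @param bandwidth Gaussian kernel standard deviations per axis (default
#'   Scott's rule).
#' @param temperature kelvin, stored for reporting kT in kJ/mol.
#' @param weights optional non-negative sample weights (normalised
#'   internally, so scaling all weights leaves the surface unchanged).
#' @return a \linkS4class{LandscapeGrid}.
#' @examples
#' xy <- cbind(rnorm(500), rnorm(500))
#' fel <- freeEnergyLandscape(xy, gridSize = c(40, 40))
#' min(fel@freeEnergy)  # 0
#' @export
freeEnergyLandscape <- function(samples, gridSize = c(100, 100),
                                bandwidth = NULL, temperature = 298,
                                weights = NULL) {
  samples <- as.matrix(samples)
  stopifnot(ncol(samples) == 2, nrow(samples) >= 2, all(is.finite(samples)))
  n <- nrow(samples)
  if (length(gridSize) == 1) gridSize <- rep(gridSize, 2)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)

  if (is.null(bandwidth)) {
    ## Scott's rule; fall back to a small positive width for degenerate axes
    bandwidth <- apply(samples, 2, sd) * n^(-1 / 6)
    bandwidth[bandwidth <= 0 | !is.finite(bandwidth)] <- 1e-3
  }
  if (length(bandwidth) == 1) bandwidth <- rep(bandwidth, 2)
  if (any(bandwidth <= 0)) stop("bandwidth must be > 0")

  axisGrid <- function(v, h, m) {
    r <- range(v)
    pad <- max(0.05 * diff(r), 3 * h, 1e-6)
    seq(r[1] - pad, r[2] + pad, length.out = m)
  }
  gx <- axisGrid(samples[, 1], bandwidth[1], gridSize[1])
  gy <- axisGrid(samples[, 2], bandwidth[2], gridSize[2])

  ## product-kernel KDE, chunked over samples to bound memory
  D <- matrix(0, length(gx), length(gy))
  chunk <- 20000L
  for (from in seq(1, n, by = chunk)) {
    to <- min(from + chunk - 1L, n)
    Ax <- outer(gx, samples[from:to, 1],
                function(g, x) dnorm(g - x, sd = bandwidth[1]))
    Ay <- outer(gy, samples[from:to, 2],
                function(g, y) dnorm(g - y, sd = bandwidth[2]))
    D <- D + Ax %*% (weights[from:to] * t(Ay))
  }
  pmax_ <- max(D)
  if (pmax_ <= 0) stop("degenerate density estimate")
  fe <- -log(D / pmax_)
  fe[D == 0] <- Inf
  new("LandscapeGrid", x = gx, y = gy, density = D, freeEnergy = fe,
      bandwidth = as.numeric(bandwidth), temperature = temperature)
}
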