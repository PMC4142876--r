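# Base-graphics rendering of landscapes and histograms.

#' Plot a free-energy landscape
#'
#' Filled-contour style image of the capped free-energy surface.
#'
#' @param fel a \linkS4class{LandscapeGrid}.
#' @param xlab,ylab axis labels.
#' @param maxG free energies above this (kT) are clipped for display.
#' @param ... passed to \code{\link[graphics]{image}}.
#' @return invisibly, NULL.
#' @export
plotLandscape <- function(fel, xlab = "coordinate 1", ylab = "coordinate 2",
                          maxG = 8, ...) {
  stopifnot(is(fel, "LandscapeGrid"))
  fe <- cappedFreeEnergy(fel)
  fe[fe > maxG] <- maxG
  graphics::image(fel@x, fel@y, fe, col = grDevices::hcl.colors(48, "viridis",
                                                                rev = TRUE),
                  xlab = xlab, ylab = ylab, useRaster = TRUE, ...)
  graphics::contour(fel@x, fel@y, fe, add = TRUE, nlevels = 8,
                    col = "grey30")
  invisible(NULL)
}

#' Plot a histogram with error bars
#'
#' @param h data.frame from \code{\link{histogramWithErrors}}.
#' @param xlab,ylab axis labels.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @return invisibly, NULL.
#' @export
plotHistogramWithErrors <- function(h, xlab = "value", ylab = "density",
                                    ...) {
  stopifnot(all(c("mid", "density", "se") %in% names(h)))
  graphics::plot(h$mid, h$density, type = "s", xlab = xlab, ylab = ylab, ...)
  ok <- is.finite(h$se)
  graphics::arrows(h$mid[ok], (h$density - h$se)[ok],
                   h$mid[ok], (h$density + h$se)[ok],
                   angle = 90, code = 3, length = 0.02, col = "grey40")
  invisible(NULL)
}
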