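# Generics, accessors and show methods.

#' Site labels of a topology or model
#' @param x a ReceptorTopology, TitrationModel or Conformation.
#' @return character vector of site labels.
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @rdname siteLabels
#' @export
setMethod("siteLabels", "ReceptorTopology", function(x) x@sites)

#' @rdname siteLabels
#' @export
setMethod("siteLabels", "TitrationModel", function(x) x@topology@sites)

#' @rdname siteLabels
#' @export
setMethod("siteLabels", "Conformation", function(x) x@topology@sites)

#' Arm and generation of each titratable site
#' @param topology a \linkS4class{ReceptorTopology}.
#' @param site site label(s) or indices; default all sites.
#' @return integer vector of arm indices (1..3) or generations (1, 2).
#' @export
armOf <- function(topology, site = topology@sites) {
  idx <- if (is.character(site)) match(site, topology@sites) else as.integer(site)
  if (anyNA(idx)) stop("unknown site label")
  topology@arm[idx]
}

#' @rdname armOf
#' @export
generationOf <- function(topology, site = topology@sites) {
  idx <- if (is.character(site)) match(site, topology@sites) else as.integer(site)
  if (anyNA(idx)) stop("unknown site label")
  topology@generation[idx]
}

#' Atom coordinates of a conformation
#' @param x a \linkS4class{Conformation}.
#' @param labels optional atom labels to subset.
#' @return numeric matrix (n x 3), nm.
#' @export
setGeneric("coords", function(x, labels = NULL) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "Conformation", function(x, labels = NULL) {
  if (is.null(labels)) return(x@coords)
  missing <- setdiff(labels, rownames(x@coords))
  if (length(missing))
    stop("unknown atom labels: ", paste(missing, collapse = ", "))
  x@coords[labels, , drop = FALSE]
})

#' Atom table of a conformation
#' @param x a \linkS4class{Conformation}.
#' @return data.frame with label, element, mol, type.
#' @export
atomTable <- function(x) {
  stopifnot(is(x, "Conformation"))
  x@atoms
}

#' Does a conformation carry the mannoside mimic?
#' @param x a \linkS4class{Conformation}.
#' @return logical.
#' @export
hasLigand <- function(x) {
  stopifnot(is(x, "Conformation"))
  any(x@atoms$mol == "ligand")
}

#' Number of frames in an ensemble
#' @param x an \linkS4class{EnsembleRecord}.
#' @return integer.
#' @export
nFrames <- function(x) {
  stopifnot(is(x, "EnsembleRecord"))
  length(x@coordsList)
}

#' Materialise one frame of an ensemble as a Conformation
#' @param x an \linkS4class{EnsembleRecord}.
#' @param i frame position (1..nFrames).
#' @return a \linkS4class{Conformation}.
#' @export
getFrame <- function(x, i) {
  stopifnot(is(x, "EnsembleRecord"), i >= 1, i <= nFrames(x))
  conf <- x@template
  conf@coords <- x@coordsList[[i]]
  conf@metadata$frame <- x@frames[i]
  if (length(x@states)) conf@metadata$state <- x@states[[i]]
  conf
}

#' Protonation states recorded along an ensemble
#' @param x an \linkS4class{EnsembleRecord}.
#' @return list of 0/1 vectors (empty list if titration was not active).
#' @export
ensembleStates <- function(x) {
  stopifnot(is(x, "EnsembleRecord"))
  x@states
}

#' Probabilities of a microstate distribution
#' @param x a \linkS4class{MicrostateDistribution}.
#' @return named numeric vector over the 2^n states.
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' @rdname probabilities
#' @export
setMethod("probabilities", "MicrostateDistribution",
          function(x) x@probabilities)

#' Per-site occupancies of a microstate distribution
#'
#' The occupancy of site i is \eqn{\sum_s P(s) s_i}.
#'
#' @param x a \linkS4class{MicrostateDistribution}.
#' @return named numeric vector, one occupancy in [0, 1] per site.
#' @export
siteOccupancy <- function(x) {
  stopifnot(is(x, "MicrostateDistribution"))
  S <- .stateMatrix(nchar(names(x@probabilities)[1]))
  occ <- as.numeric(crossprod(S, x@probabilities))
  names(occ) <- if (length(occ) == length(x@topology@sites))
    x@topology@sites else paste0("site", seq_along(occ))
  occ
}

#' Mean total protonation of a microstate distribution
#' @param x a \linkS4class{MicrostateDistribution}.
#' @return mean number of protons bound.
#' @export
totalProtonation <- function(x) sum(siteOccupancy(x))

#' Mean protonation per generation
#' @param x a \linkS4class{MicrostateDistribution}.
#' @return numeric(2): mean occupancy of generation-1 and generation-2 sites.
#' @export
generationOccupancy <- function(x) {
  occ <- siteOccupancy(x)
  gen <- x@topology@generation
  c(gen1 = mean(occ[gen == 1L]), gen2 = mean(occ[gen == 2L]))
}

#' Titration-curve table
#' @param x a \linkS4class{TitrationCurve}.
#' @return the data.frame of occupancies against pH.
#' @export
curveTable <- function(x) {
  stopifnot(is(x, "TitrationCurve"))
  x@curve
}

#' Free energy surface with zero-density bins capped
#'
#' Bins with zero estimated density carry +Inf in the raw surface; for
#' plotting they are replaced by a finite cap,
#' \eqn{-\ln(\epsilon / P_{max})} with \eqn{\epsilon} a machine-scale floor.
#'
#' @param x a \linkS4class{LandscapeGrid}.
#' @return matrix of free energies in kT units, all finite.
#' @export
cappedFreeEnergy <- function(x) {
  stopifnot(is(x, "LandscapeGrid"))
  fe <- x@freeEnergy
  pmax_ <- max(x@density)
  cap <- -log(.Machine$double.xmin / pmax_)
  fe[!is.finite(fe)] <- cap
  fe
}

## ---- show methods -------------------------------------------------------

setMethod("show", "ReceptorTopology", function(object) {
  cat("ReceptorTopology: 3 arms, 6 titratable amine sites\n")
  cat("  sites:", paste(object@sites, collapse = " "), "\n")
})

setMethod("show", "Conformation", function(object) {
  n <- nrow(object@coords)
  lig <- if (hasLigand(object)) "with mannoside mimic" else "receptor only"
  cat(sprintf("Conformation: %d atoms (%s)\n", n, lig))
  if (!is.null(object@metadata$openness))
    cat(sprintf("  openness: %.3f\n", object@metadata$openness))
})

setMethod("show", "EnsembleRecord", function(object) {
  cat(sprintf("EnsembleRecord: %d frames%s\n", nFrames(object),
              if (length(object@states)) " (with protonation states)" else ""))
  if (!is.null(object@metadata$pH))
    cat(sprintf("  pH: %s\n", format(object@metadata$pH)))
})

setMethod("show", "TitrationModel", function(object) {
  cat("TitrationModel: 6 sites\n")
  cat("  pKint:", paste(format(object@pKint, digits = 4), collapse = " "), "\n")
  cat(sprintf("  max coupling: %.2f pK units; pairs above 2.0: %d\n",
              max(object@W), sum(object@W[upper.tri(object@W)] > 2)))
})

setMethod("show", "MicrostateDistribution", function(object) {
  cat(sprintf("MicrostateDistribution (%s) at pH %.2f\n",
              object@method, object@pH))
  cat(sprintf("  mean total protonation: %.3f\n", totalProtonation(object)))
})

setMethod("show", "TitrationCurve", function(object) {
  cat(sprintf("TitrationCurve (%s engine), %d pH values in [%.2f, %.2f]\n",
              object@engine, nrow(object@curve), min(object@curve$pH),
              max(object@curve$pH)))
})

setMethod("show", "LandscapeGrid", function(object) {
  cat(sprintf("LandscapeGrid: %d x %d bins, bandwidth (%.3g, %.3g)\n",
              length(object@x), length(object@y),
              object@bandwidth[1], object@bandwidth[2]))
})

setMethod("show", "SeriesError", function(object) {
  cat(sprintf("SeriesError: mean %.4g +/- %.4g (g = %.2f, Neff = %.0f)\n",
              object@mean, object@se, object@inefficiency, object@neff))
})
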