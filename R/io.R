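# Plain-text structure I/O: extended XYZ (element, x, y, z, label) and
# minimal PDB (HETATM records with atom names encoding the bead labels).

#' Write conformations as (multi-frame) XYZ
#'
#' Extended XYZ: after the element and the three coordinates (nm), a fifth
#' column carries the bead label so files written by this package round-trip
#' through \code{\link{readXYZ}}.
#'
#' @param x a \linkS4class{Conformation} or \linkS4class{EnsembleRecord}.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeXYZ <- function(x, file) {
  frames <- if (is(x, "EnsembleRecord")) {
    lapply(seq_len(nFrames(x)), function(i) getFrame(x, i))
  } else {
    stopifnot(is(x, "Conformation"))
    list(x)
  }
  con <- file(file, "w")
  on.exit(close(con))
  for (f in frames) {
    X <- f@coords
    writeLines(as.character(nrow(X)), con)
    writeLines(sprintf("frame openness=%s",
                       format(f@metadata$openness %||% NA)), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f %s",
                       f@atoms$element, X[, 1], X[, 2], X[, 3],
                       f@atoms$label), con)
  }
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read (multi-frame) XYZ
#'
#' @param file path to an XYZ file; a fifth column, when present, is taken
#'   as the atom label (files written by \code{\link{writeXYZ}} have one).
#' @return list of \linkS4class{Conformation}s when labels are present,
#'   otherwise a list of bare coordinate matrices with element rownames.
#' @export
readXYZ <- function(file) {
  lines <- readLines(file)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected an atom count at line ", i)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    X <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    hasLabels <- all(lengths(parts) >= 5)
    if (hasLabels) {
      rownames(X) <- vapply(parts, `[`, character(1), 5)
      out[[length(out) + 1L]] <- conformationFromCoords(X)
    } else {
      rownames(X) <- make.unique(vapply(parts, `[`, character(1), 1))
      out[[length(out) + 1L]] <- X
    }
    i <- i + 2L + n
  }
  out
}

## PDB atom names are at most 4 characters: compress the bead labels.
.pdbName <- function(labels) {
  out <- labels
  out <- sub("^NP\\.a([1-3])$", "NP\\1", out)
  out <- sub("^HNP\\.a([1-3])$", "HP\\1", out)
  out <- sub("^N\\.a([1-3])\\.g([12])$", "N\\1\\2", out)
  out <- sub("^H\\.a([1-3])\\.g([12])$", "H\\1\\2", out)
  out
}

.labelFromPdbName <- function(names) {
  out <- names
  out <- sub("^NP([1-3])$", "NP.a\\1", out)
  out <- sub("^HP([1-3])$", "HNP.a\\1", out)
  out <- sub("^N([1-3])([12])$", "N.a\\1.g\\2", out)
  out <- sub("^H([1-3])([12])$", "H.a\\1.g\\2", out)
  out
}

#' Write a conformation as a minimal PDB
#'
#' HETATM records only; coordinates are converted from nm to Angstrom.
#' Residue TRI holds the receptor, MAN the mannoside mimic; atom names
#' encode the bead labels and round-trip through \code{\link{readPDB}}.
#'
#' @param conf a \linkS4class{Conformation}.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writePDB <- function(conf, file) {
  stopifnot(is(conf, "Conformation"))
  at <- conf@atoms
  X <- conf@coords * 10  # nm -> Angstrom
  res <- ifelse(at$mol == "receptor", "TRI", "MAN")
  resid <- ifelse(at$mol == "receptor", 1L, 2L)
  lines <- sprintf(
    "HETATM%5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(X)), .pdbName(at$label), res, resid,
    X[, 1], X[, 2], X[, 3], at$element)
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Read a minimal PDB written by this package
#'
#' @param file path.
#' @return a \linkS4class{Conformation} (coordinates back in nm).
#' @export
readPDB <- function(file) {
  lines <- grep("^HETATM", readLines(file), value = TRUE)
  if (!length(lines)) stop("no HETATM records in ", file)
  name <- trimws(substr(lines, 13, 16))
  X <- cbind(as.numeric(substr(lines, 31, 38)),
             as.numeric(substr(lines, 39, 46)),
             as.numeric(substr(lines, 47, 54))) / 10
  rownames(X) <- .labelFromPdbName(name)
  conformationFromCoords(X)
}
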