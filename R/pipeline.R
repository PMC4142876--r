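# End-to-end studies: titration curves and microstate classes, pH-resolved
# conformational analysis, and receptor/mannoside interaction histograms,
# with config validation, derived replicate seeds and provenance headers on
# every output file.

## Named protonation states of the receptor + mannoside runs; the q3/q4
## states are the pH-representative patterns (charges placed to minimise
## repulsion: second generation first, extra protons on distinct arms).
.STATE_LABELS <- c("Wq0", "Wq3a", "Wq3b", "Wq4", "aprotic")

#' Protonation state vector from a study label
#'
#' Accepted labels (the caret is optional): \code{W^q0} (fully
#' deprotonated), \code{W^q3a} (3 protons in generation 2), \code{W^q3b}
#' (2 in generation 2 + 1 in generation 1), \code{W^q4} (3 in generation 2
#' + 1 in generation 1) and \code{aprotic} (fully deprotonated, titration
#' inactive).
#'
#' @param label state label.
#' @param topology a \linkS4class{ReceptorTopology}.
#' @return 0/1 vector over the six sites.
#' @examples
#' protonationStateFromLabel("W^q3a")
#' @export
protonationStateFromLabel <- function(label,
                                      topology = buildReceptorTopology()) {
  lab <- gsub("\\^", "", label)
  if (!lab %in% .STATE_LABELS)
    stop("unknown protonation state label: ", label,
         " (known: ", paste(.STATE_LABELS, collapse = ", "), ")")
  s <- integer(6)
  g1 <- which(topology@generation == 1L)
  g2 <- which(topology@generation == 2L)
  if (lab == "Wq3a") s[g2] <- 1L
  if (lab == "Wq3b") { s[g2[1:2]] <- 1L; s[g1[3]] <- 1L }
  if (lab == "Wq4") { s[g2] <- 1L; s[g1[1]] <- 1L }
  s
}

## Deterministic replicate/stream seed derivation from the master seed.
.deriveSeed <- function(master, index) {
  as.integer((as.numeric(master) * 1009 + 97 * index) %% 2147483629 + 1)
}

## Order-independent provenance hash of the resolved config (Horner over
## the deparsed key=value pairs).
.configHash <- function(config) {
  config$outDir <- NULL
  keys <- sort(names(config))
  txt <- paste(keys, vapply(config[keys], function(v)
    paste(deparse(v), collapse = ""), character(1)),
    sep = "=", collapse = ";")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.writeStudyCSV <- function(df, file, config) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# tripodCpH %s", as.character(packageVersion("tripodCpH"))),
    sprintf("# seed: %d", config$seed),
    sprintf("# config_hash: %s", .configHash(config))), con)
  write.table(format(df, digits = 10, trim = TRUE), con, sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Validate and normalise a study configuration
#'
#' Checks invariants, fills documented defaults and returns the resolved
#' config; unknown keys draw a warning (forward compatibility), a missing
#' seed is an error.  pH grids may be given as numeric vectors or as
#' \code{"from:to:step"} strings (\code{"1:10:1"} expands to the ten
#' integer values).
#'
#' @param config named list; \code{seed} is mandatory, \code{pHGrid} is
#'   mandatory in the aqueous regime.
#' @return the resolved config (class \code{RunConfig}), with components
#'   seed, regime ("aqueous"/"aprotic"), pHGrid, replicates (3), nCycles
#'   (2000), mcStepsPerCycle (1000), mcSteps (1e5), engine ("mc"), nFrames
#'   (500), noise (0.02), maxRingSeparation (1.0), outDir.
#' @examples
#' cfg <- validateConfig(list(seed = 1, pHGrid = "1:10:1"))
#' cfg$pHGrid
#' @export
validateConfig <- function(config) {
  stopifnot(is.list(config))
  defaults <- list(
    seed = NULL, regime = "aqueous", pHGrid = NULL, replicates = 3L,
    nCycles = 2000L, mcStepsPerCycle = 1000L, mcSteps = 1e5,
    engine = "mc", nFrames = 500L, noise = 0.02, maxRingSeparation = 1.0,
    referenceOpenness = 0.3, outDir = file.path(tempdir(), "tripodCpH-run"))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (k in intersect(names(config), names(defaults))) cfg[[k]] <- config[[k]]

  errs <- character()
  if (is.null(cfg$seed)) errs <- c(errs, "'seed' is mandatory")
  else cfg$seed <- as.integer(cfg$seed)
  if (!cfg$regime %in% c("aqueous", "aprotic"))
    errs <- c(errs, "'regime' must be aqueous or aprotic")
  if (is.character(cfg$pHGrid)) {
    parts <- suppressWarnings(as.numeric(strsplit(cfg$pHGrid, ":")[[1]]))
    if (length(parts) != 3 || anyNA(parts) || parts[3] <= 0)
      errs <- c(errs, "pH grid string must be 'from:to:step'")
    else cfg$pHGrid <- seq(parts[1], parts[2], by = parts[3])
  }
  if (identical(cfg$regime, "aqueous") && !length(cfg$pHGrid))
    errs <- c(errs, "'pHGrid' is required in the aqueous regime")
  counts <- c("replicates", "nCycles", "mcStepsPerCycle", "mcSteps",
              "nFrames")
  for (k in counts) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 1)
      errs <- c(errs, sprintf("'%s' must be a positive count", k))
  }
  if (!cfg$engine %in% c("mc", "exact"))
    errs <- c(errs, "'engine' must be mc or exact")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  class(cfg) <- c("RunConfig", "list")
  cfg
}

## Echo the resolved config into the output directory for provenance.
.echoConfig <- function(config) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  keys <- setdiff(names(config), "outDir")
  writeLines(c(
    sprintf("# tripodCpH %s  config_hash %s",
            as.character(packageVersion("tripodCpH")), .configHash(config)),
    vapply(keys, function(k)
      paste0(k, " = ", paste(deparse(config[[k]]), collapse = " ")),
      character(1))),
    file.path(config$outDir, "config_resolved.txt"))
}

## Conformational-only Metropolis ensemble at a fixed protonation state
## (titration inactive: the aprotic regime and the fixed-state
## receptor+mannoside runs).
.fixedStateEnsemble <- function(state, nCycles, seed, noise = 0,
                                initialOpenness = 0.5) {
  coupledCpHLoop(pH = NA_real_, nCycles = nCycles, seed = seed,
                 confMovesPerCycle = 5,
                 initialOpenness = initialOpenness, noise = noise,
                 fixedState = as.integer(state))
}

#' Run the titration study (titration curve + microstate classes)
#'
#' For each pH on the grid, runs the configured number of coupled-loop
#' replicates, discards the first 10\% of each trajectory, and aggregates
#' per-site occupancies into the total titration curve, per-generation
#' percentages (replicate-level standard errors) and arm-symmetry class
#' populations pooled over all pH values.  Writes
#' \code{titration_curve.csv} and \code{microstate_classes.csv} into the
#' output directory; outputs are reproducible from (config, seed).
#'
#' @param config a config list or \code{RunConfig} (aqueous regime).
#' @return invisibly, list(curve, classes).
#' @export
runTitrationStudy <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config else validateConfig(config)
  if (cfg$regime != "aqueous") stop("the titration study needs the aqueous regime")
  .echoConfig(cfg)
  topo <- buildReceptorTopology()
  gen <- generationOf(topo)
  stream <- 0L
  rows <- list()
  pooled <- numeric(64)
  for (pH in cfg$pHGrid) {
    repTotals <- numeric(cfg$replicates)
    repOcc <- matrix(0, cfg$replicates, 6)
    for (r in seq_len(cfg$replicates)) {
      stream <- stream + 1L
      ens <- coupledCpHLoop(pH = pH, nCycles = cfg$nCycles,
                            seed = .deriveSeed(cfg$seed, stream),
                            mcStepsPerCycle = cfg$mcStepsPerCycle,
                            noise = 0)
      keep <- seq(floor(0.1 * cfg$nCycles) + 1L, cfg$nCycles)
      S <- do.call(rbind, ens@states[keep])
      repOcc[r, ] <- colMeans(S)
      repTotals[r] <- sum(colMeans(S))
      idx <- as.integer(S %*% 2^(0:5)) + 1L
      pooled <- pooled + tabulate(idx, nbins = 64)
    }
    occ <- colMeans(repOcc)
    se <- if (cfg$replicates > 1) sd(repTotals) / sqrt(cfg$replicates) else NA
    rows[[length(rows) + 1L]] <- c(
      pH = pH, total = sum(occ), total_se = se,
      gen1_percent = 100 * mean(occ[gen == 1L]),
      gen2_percent = 100 * mean(occ[gen == 2L]),
      setNames(occ, paste0("occ.", topo@sites)))
  }
  curve <- as.data.frame(do.call(rbind, rows))
  pooledDist <- new("MicrostateDistribution",
                    probabilities = setNames(pooled / sum(pooled),
                                             rownames(.stateMatrix(6))),
                    method = "mc", pH = NA_real_, nSamples = sum(pooled),
                    topology = topo)
  classes <- classifyMicrostates(pooledDist)
  .writeStudyCSV(curve, file.path(cfg$outDir, "titration_curve.csv"), cfg)
  .writeStudyCSV(classes, file.path(cfg$outDir, "microstate_classes.csv"),
                 cfg)
  invisible(list(curve = curve, classes = classes))
}

#' Run the conformational study (Rg histograms, landscapes, arm positions)
#'
#' For each aqueous pH and the aprotic regime, generates a coupled-loop
#' ensemble, computes the per-frame radius of gyration and
#' symmetry-corrected RMSD against the canonical reference conformation,
#' and emits Rg histograms (autocorrelation-corrected errors), the RMSD x
#' Rg free-energy landscape and the pyrrolic-nitrogen arm-position table
#' (up to 900 frames) per regime.
#'
#' @param config a config list or \code{RunConfig}.
#' @return invisibly, a list per regime with rg, rmsd, histogram,
#'   landscape, armPositions.
#' @export
runConformationStudy <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config else validateConfig(config)
  .echoConfig(cfg)
  ref <- generateConformation(cfg$referenceOpenness, seed = 20140703L,
                              noise = 0)
  regimes <- c(if (length(cfg$pHGrid)) paste0("pH", cfg$pHGrid), "aprotic")
  out <- list()
  stream <- 1000L
  for (reg in regimes) {
    stream <- stream + 1L
    ens <- if (reg == "aprotic") {
      .fixedStateEnsemble(integer(6), cfg$nCycles,
                          .deriveSeed(cfg$seed, stream), noise = 0)
    } else {
      coupledCpHLoop(pH = as.numeric(sub("pH", "", reg)),
                     nCycles = cfg$nCycles,
                     seed = .deriveSeed(cfg$seed, stream),
                     mcStepsPerCycle = cfg$mcStepsPerCycle, noise = 0)
    }
    keep <- seq(floor(0.1 * nFrames(ens)) + 1L, nFrames(ens))
    rg <- vapply(keep, function(i) radiusOfGyration(getFrame(ens, i)),
                 numeric(1))
    rmsd <- vapply(keep, function(i) symmetryRMSD(getFrame(ens, i), ref),
                   numeric(1))
    hist <- histogramWithErrors(rg, breaks = seq(0.4, 0.85, by = 0.015))
    fel <- freeEnergyLandscape(cbind(rmsd, rg), gridSize = c(60, 60))
    armIdx <- keep[seq_len(min(900, length(keep)))]
    arms <- do.call(rbind, lapply(armIdx, function(i) {
      ap <- armPositions(getFrame(ens, i))
      data.frame(frame = i, arm = 1:3, x = ap[, 1], y = ap[, 2],
                 z = ap[, 3])
    }))
    .writeStudyCSV(hist,
                   file.path(cfg$outDir, sprintf("rg_histogram_%s.csv", reg)),
                   cfg)
    grid <- expand.grid(rmsd = fel@x, rg = fel@y)
    grid$density <- as.numeric(fel@density)
    grid$free_energy <- as.numeric(cappedFreeEnergy(fel))
    .writeStudyCSV(grid,
                   file.path(cfg$outDir, sprintf("landscape_%s.csv", reg)),
                   cfg)
    .writeStudyCSV(arms,
                   file.path(cfg$outDir,
                             sprintf("arm_positions_%s.csv", reg)), cfg)
    out[[reg]] <- list(rg = rg, rmsd = rmsd, histogram = hist,
                       landscape = fel, armPositions = arms)
  }
  invisible(out)
}

## Pose mixture per protonation-state label: the aprotic solvent favours
## the hydrogen-bonded head pose, the neutral aqueous receptor the
## hydrophobically stacked tail pose, and first-generation protonation
## disrupts both specific modes.
.POSE_WEIGHTS <- list(
  aprotic = c(head = 0.60, loose = 0.35, tail = 0.05),
  Wq0     = c(head = 0.05, loose = 0.35, tail = 0.60),
  Wq3a    = c(head = 0.20, loose = 0.50, tail = 0.30),
  Wq3b    = c(head = 0.20, loose = 0.70, tail = 0.10),
  Wq4     = c(head = 0.20, loose = 0.70, tail = 0.10))

#' Run the receptor/mannoside interaction study
#'
#' For each named protonation state (and the aprotic regime), generates a
#' fixed-state conformational ensemble, places the mannoside mimic with a
#' state-dependent pose mixture inside the ring-ring restraint sphere, and
#' emits the hydrogen-bond count and tail-ring distance histograms plus
#' per-frame observables (including the restraint energy).
#'
#' @param config a config list or \code{RunConfig}.
#' @param states state labels (default all five).
#' @return invisibly, a list per state with perFrame, hbondHistogram,
#'   distanceHistogram.
#' @export
runInteractionStudy <- function(config, states = .STATE_LABELS) {
  cfg <- if (inherits(config, "RunConfig")) config else validateConfig(config)
  .echoConfig(cfg)
  out <- list()
  stream <- 2000L
  for (lab in states) {
    s <- protonationStateFromLabel(lab)
    stream <- stream + 1L
    recEns <- .fixedStateEnsemble(s, cfg$nFrames,
                                  .deriveSeed(cfg$seed, stream), noise = 0)
    w <- .POSE_WEIGHTS[[gsub("\\^", "", lab)]]
    poses <- withSeed(.deriveSeed(cfg$seed, stream + 500L),
                      sample(names(w), cfg$nFrames, replace = TRUE, prob = w))
    bound <- lapply(seq_len(cfg$nFrames), function(i)
      placeMannoside(getFrame(recEns, i),
                     poseSeed = .deriveSeed(cfg$seed, stream * 10000L + i),
                     maxRingSeparation = cfg$maxRingSeparation,
                     pose = poses[i]))
    ens <- new("EnsembleRecord", template = bound[[1]],
               coordsList = lapply(bound, function(b) b@coords),
               states = rep(list(as.integer(s)), cfg$nFrames),
               frames = seq_len(cfg$nFrames),
               metadata = list(state = lab, seed = cfg$seed))
    res <- interactionHistograms(ens,
                                 distBreaks = seq(0, 4, by = 0.1))
    slug <- gsub("\\^", "", lab)
    .writeStudyCSV(res$perFrame,
                   file.path(cfg$outDir, sprintf("perframe_%s.csv", slug)),
                   cfg)
    .writeStudyCSV(res$hbondHistogram,
                   file.path(cfg$outDir, sprintf("hbond_hist_%s.csv", slug)),
                   cfg)
    .writeStudyCSV(res$distanceHistogram,
                   file.path(cfg$outDir, sprintf("dist_hist_%s.csv", slug)),
                   cfg)
    out[[lab]] <- res
  }
  invisible(out)
}
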