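# Microstate energetics, exact enumeration, Metropolis MC and curve fits.

test_that("microstate energy follows the multi-site free energy", {
  m <- titrationModel(10.64, 0)
  expect_equal(microstateEnergy(rep(0, 6), m, 7), 0)
  expect_equal(microstateEnergy(c(1, 0, 0, 0, 0, 0), m, 7), 7 - 10.64)
  ## two protonated sites with W = 2 at pH = pKa: only the coupling remains
  m2 <- titrationModel(10.64, 2)
  expect_equal(microstateEnergy(c(1, 0, 0, 1, 0, 0), m2, 10.64), 2.0)
  expect_error(microstateEnergy(c(2, 0, 0, 0, 0, 0), m, 7), "0/1")
})

test_that("exact enumeration recovers the independent-site limits", {
  m <- titrationModel(10.64, 0)
  d <- enumerateEquilibrium(m, 10.64)
  expect_equal(unname(siteOccupancy(d)), rep(0.5, 6), tolerance = 1e-12)
  ## extreme pH: fully protonated state dominates
  mB <- titrationModel(10.64, 1)
  lo <- enumerateEquilibrium(mB, 10.64 - 10)
  expect_gt(probabilities(lo)[["111111"]], 0.99)
  hi <- enumerateEquilibrium(mB, 10.64 + 10)
  expect_gt(probabilities(hi)[["000000"]], 0.99)
  ## normalisation and the occupancy identity
  mr <- titrationModel(c(9, 10, 11, 10.5, 10, 12),
                       matrix(1, 6, 6) - diag(6))
  dr <- enumerateEquilibrium(mr, 10)
  p <- probabilities(dr)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  S <- tripodCpH:::.stateMatrix(6)
  expect_equal(unname(siteOccupancy(dr)), as.numeric(crossprod(S, p)))
})

test_that("MC titration reproduces exact enumeration", {
  m <- titrationModel(10.64, 0)
  dm <- mcTitration(m, 10.64, nSteps = 1e5, seed = 1)
  expect_true(all(abs(siteOccupancy(dm) - 0.5) < 0.02))
  de <- enumerateEquilibrium(m, 10.64)
  expect_lt(tvd(probabilities(dm), probabilities(de)), 0.02)
  ## reproducible under the seed
  dm2 <- mcTitration(m, 10.64, nSteps = 1e4, seed = 7)
  dm3 <- mcTitration(m, 10.64, nSteps = 1e4, seed = 7)
  expect_identical(probabilities(dm2), probabilities(dm3))
})

test_that("a strongly coupled pair is anti-correlated, matching enumeration", {
  W <- matrix(0, 6, 6)
  W[1, 4] <- W[4, 1] <- 8
  m <- titrationModel(10.64, W)
  de <- enumerateEquilibrium(m, 10.64)
  dm <- mcTitration(m, 10.64, nSteps = 1e5, seed = 3)
  S <- tripodCpH:::.stateMatrix(6)
  joint <- function(p) sum(p[S[, 1] == 1 & S[, 4] == 1])
  occ <- siteOccupancy(dm)
  expect_lt(joint(probabilities(dm)), 0.2 * occ[1] * occ[4])
  expect_lt(tvd(probabilities(dm), probabilities(de)), 0.02)
  ## the pair move list picked up the strong coupling
  res <- mcSampleStates(m@pKint, m@W, 10.64, nSteps = 10, seed = 1)
  expect_equal(res$nPairs, 1)
})

test_that("a 2-site chain reproduces the analytic 4-state Boltzmann law", {
  pK <- c(10, 9); w <- 3; pH <- 9.5
  ## independent hand evaluation of the four state weights
  g <- c(`00` = 0, `10` = pH - pK[1], `01` = pH - pK[2],
         `11` = (pH - pK[1]) + (pH - pK[2]) + w)
  pTrue <- 10^(-g) / sum(10^(-g))
  W2 <- matrix(c(0, w, w, 0), 2)
  res <- mcSampleStates(pK, W2, pH, nSteps = 2e5, seed = 11)
  expect_lt(tvd(res$probabilities, pTrue), 0.01)
})

test_that("pair moves change acceptance statistics, not the distribution", {
  set.seed(21)
  W <- matrix(0, 6, 6)
  W[upper.tri(W)] <- rexp(15, rate = 1 / 1.5)
  W <- W + t(W)
  m <- titrationModel(runif(6, 9.5, 11.5), W)
  de <- enumerateEquilibrium(m, 10.5)
  withPairs <- mcSampleStates(m@pKint, m@W, 10.5, nSteps = 1e5, seed = 5,
                              pairThreshold = 2)
  noPairs <- mcSampleStates(m@pKint, m@W, 10.5, nSteps = 1e5, seed = 5,
                            pairThreshold = Inf)
  expect_gt(withPairs$nPairs, 0)
  expect_equal(noPairs$nPairs, 0)
  expect_lt(tvd(withPairs$probabilities, probabilities(de)), 0.02)
  expect_lt(tvd(noPairs$probabilities, probabilities(de)), 0.02)
})

test_that("titration curves aggregate occupancies correctly", {
  m <- titrationModel(10.64, 0)
  tc <- curveTable(titrationCurve(m, 10.64))
  expect_equal(tc$total, 3.0, tolerance = 1e-12)
  ## monotone non-increasing total with pH for a pH-independent model
  pm <- plateauCalibrationModel()
  cv <- curveTable(titrationCurve(pm, 0:14))
  expect_true(all(diff(cv$total) <= 1e-9))
  expect_gte(cv$total[cv$pH == 0], cv$total[cv$pH == 14])
  ## the calibrated plateau: total ~3 carried by generation 2
  at6 <- cv[cv$pH == 6, ]
  expect_equal(at6$total, 3, tolerance = 0.05)
  expect_gt(at6$gen2_percent, 99)
  expect_lt(at6$gen1_percent, 1)
  expect_error(titrationCurve(m, 1:3, engine = "mc"), "seed")
})

test_that("apparent-pKa fits recover the model inputs", {
  grid <- seq(8, 13, by = 0.1)
  occ <- vapply(grid, function(p)
    enumerateStates(10.64, matrix(0, 1, 1), p)$occupancy, numeric(1))
  fit <- fitApparentPKa(grid, occ)
  expect_equal(fit$pKa, 10.64, tolerance = 0.01)
  ## a constant repulsion w shifts the midpoint to pKint - w
  w <- 1.7
  occShift <- 1 / (1 + 10^(grid - (10.64 - w)))
  fitS <- fitApparentPKa(grid, occShift)
  expect_equal(fitS$pKa, 10.64 - w, tolerance = 0.01)
  expect_error(fitApparentPKa(grid, rep(1, length(grid))),
               "non-identifiable")
})

test_that("microstate classes match the brute-force orbit oracle", {
  d <- enumerateEquilibrium(plateauCalibrationModel(), 6)
  cls <- classifyMicrostates(d)
  expect_equal(unname(table(cls$n)), array(c(1L, 2L, 4L, 6L, 4L, 2L, 1L)),
               ignore_attr = TRUE)
  oracle <- orbitOracle()
  expect_setequal(cls$representative, unique(oracle$reps))
  ## classes within each n partition all C(6, n) states
  for (k in 0:6) {
    expect_equal(sum(cls$nStates[cls$n == k]), choose(6, k))
  }
  ## conditional populations sum to 1 for each n with mass
  pops <- tapply(cls$population, cls$n, sum)
  expect_equal(as.numeric(pops), rep(1, 7), tolerance = 1e-9)
})

test_that("class populations decrease with the class repulsion energy", {
  ## arm-symmetric model from ideal geometry: within each n, the least
  ## repulsive arrangement is the most populated
  conf <- generateConformation(0.4, seed = 13, noise = 0)
  m <- titrationModelFromConformation(conf)
  d <- enumerateEquilibrium(m, 10.64)
  cls <- classifyMicrostates(d)
  repE <- vapply(cls$representative, function(k) {
    s <- as.numeric(strsplit(k, "")[[1]])
    0.5 * drop(s %*% m@W %*% s)
  }, numeric(1))
  for (k in 1:5) {
    i <- cls$n == k
    ord <- order(repE[i])
    ## per-state population (class population over orbit size) is
    ## non-increasing in the class repulsion energy
    perState <- (cls$population[i] / cls$nStates[i])[ord]
    expect_true(all(diff(perState) <= 1e-9))
    ## and the top class minimises the repulsion among classes of its size
    best <- which.max(cls$population[i] / cls$nStates[i])
    expect_equal(unname(repE[i][best]), min(repE[i]))
  }
})

test_that("coupled loop with a frozen conformation matches enumeration", {
  ens <- coupledCpHLoop(pH = 10.2, nCycles = 400, seed = 8,
                        confMover = frozenMover(),
                        mcStepsPerCycle = 400, initialOpenness = 0.4)
  conf <- getFrame(ens, 1)
  expect_equal(conf@metadata$openness, 0.4)
  m <- titrationModelFromConformation(conf)
  de <- enumerateEquilibrium(m, 10.2)
  S <- do.call(rbind, ensembleStates(ens))
  expect_true(all(abs(colMeans(S) - siteOccupancy(de)) < 0.06))
  ## base case: one cycle yields one frame with a valid state
  one <- coupledCpHLoop(pH = 7, nCycles = 1, seed = 2,
                        mcStepsPerCycle = 100)
  expect_equal(nFrames(one), 1)
  expect_true(all(ensembleStates(one)[[1]] %in% 0:1))
  ## reproducibility
  a <- coupledCpHLoop(pH = 5, nCycles = 20, seed = 4, mcStepsPerCycle = 100)
  b <- coupledCpHLoop(pH = 5, nCycles = 20, seed = 4, mcStepsPerCycle = 100)
  expect_identical(a@metadata$openness, b@metadata$openness)
  expect_identical(ensembleStates(a), ensembleStates(b))
})

test_that("low pH opens the receptor, high pH leaves it compact", {
  prot <- coupledCpHLoop(pH = 1, nCycles = 300, seed = 31,
                         mcStepsPerCycle = 300)
  neut <- coupledCpHLoop(pH = 13, nCycles = 300, seed = 32,
                         mcStepsPerCycle = 300)
  keep <- 31:300
  expect_gt(mean(prot@metadata$openness[keep]),
            mean(neut@metadata$openness[keep]))
})
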