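# Rg, symmetry-corrected RMSD, arm positions, landscapes and error bars.

test_that("radius of gyration follows its definition", {
  conf <- generateConformation(0.5, seed = 1, noise = 0)
  ## single atom: a point mass has Rg 0
  expect_equal(radiusOfGyration(conf, selection = "C1"), 0)
  ## six unit-mass ring atoms at 0.139 nm from their centroid
  expect_equal(radiusOfGyration(conf, selection = conf@topology@ringAtoms),
               0.139, tolerance = 1e-12)
  expect_error(radiusOfGyration(conf, selection = character()), "empty")
  ## rigid-motion invariance
  for (s in 1:5) {
    moved <- rigidCopy(conf, seed = s)
    expect_equal(radiusOfGyration(moved), radiusOfGyration(conf),
                 tolerance = 1e-9)
  }
})

test_that("symmetry RMSD vanishes on orbit-equivalent conformations", {
  conf <- generateConformation(0.4, seed = 9)
  expect_equal(symmetryRMSD(conf, conf), 0, tolerance = 1e-9)
  ## a cyclic arm relabelling is absorbed by the minimum
  X <- coords(conf)
  perm <- tripodCpH:::.atomPermutation(conf@topology, c(2L, 3L, 1L),
                                       rownames(X))
  Xrel <- X[match(rownames(X), perm), ]
  rownames(Xrel) <- rownames(X)
  relabeled <- conformationFromCoords(Xrel)
  expect_equal(symmetryRMSD(relabeled, conf), 0, tolerance = 1e-9)
  ## and a rigidly moved relabelled copy is still in the orbit
  expect_equal(symmetryRMSD(rigidCopy(relabeled, 3), conf), 0,
               tolerance = 1e-9)
})

test_that("symmetry RMSD equals the brute-force minimum over relabellings", {
  set.seed(14)
  sel <- NULL
  for (i in 1:30) {
    a <- generateConformation(runif(1), seed = sample.int(1e6, 1))
    b <- generateConformation(runif(1), seed = sample.int(1e6, 1))
    if (is.null(sel))
      sel <- tripodCpH:::.receptorHeavySelection(a)
    got <- symmetryRMSD(a, b)
    ## oracle: explicit loop over the cyclic relabellings with an
    ## independent quaternion superposition
    brute <- min(vapply(list(c(1L,2L,3L), c(2L,3L,1L), c(3L,1L,2L)),
      function(p) {
        lab <- tripodCpH:::.atomPermutation(a@topology, p, sel)
        hornRMSD(coords(a, lab), coords(b, sel))
      }, numeric(1)))
    expect_equal(got, brute, tolerance = 1e-8)
    ## never worse than the unpermuted fit
    expect_lte(got, hornRMSD(coords(a, sel), coords(b, sel)) + 1e-12)
  }
})

test_that("symmetry RMSD behaves as a pseudo-metric", {
  set.seed(15)
  confs <- lapply(1:6, function(i)
    generateConformation(runif(1), seed = sample.int(1e6, 1)))
  for (i in 1:5) {
    a <- confs[[i]]; b <- confs[[i + 1]]
    expect_equal(symmetryRMSD(a, b), symmetryRMSD(b, a), tolerance = 1e-8)
  }
  for (i in 1:4) {
    a <- confs[[i]]; b <- confs[[i + 1]]; cc <- confs[[i + 2]]
    expect_lte(symmetryRMSD(a, cc),
               symmetryRMSD(a, b) + symmetryRMSD(b, cc) + 1e-8)
  }
})

test_that("arm positions live in a rigid-motion covariant ring frame", {
  conf <- generateConformation(0.6, seed = 21)
  ap <- armPositions(conf)
  for (s in 1:5) {
    expect_equal(armPositions(rigidCopy(conf, s)), ap, tolerance = 1e-8)
  }
  ## with an exactly coplanar ring, z equals the signed plane distance
  ring <- coords(conf, conf@topology@ringAtoms)
  expect_equal(unname(ap[, "z"]),
               unname(coords(conf, conf@topology@pyrrolicAtoms)[, 3] -
                        mean(ring[, 3])), tolerance = 1e-9)
  ## open arms reach out radially much farther than closed arms
  radial <- function(o) {
    p <- armPositions(generateConformation(o, seed = 3, noise = 0))
    mean(sqrt(p[, 1]^2 + p[, 2]^2))
  }
  expect_gt(radial(1), radial(0))
})

test_that("landscape estimator is normalised with its minimum at zero", {
  set.seed(31)
  xy <- cbind(rnorm(2000), rnorm(2000))
  fel <- freeEnergyLandscape(xy, gridSize = c(50, 50))
  dx <- mean(diff(fel@x)); dy <- mean(diff(fel@y))
  expect_equal(sum(fel@density) * dx * dy, 1, tolerance = 0.01)
  expect_equal(min(fel@freeEnergy), 0)
  expect_true(all(fel@density >= 0))
  ## degenerate input: a single repeated point gives a single increasing well
  pt <- cbind(rep(1.5, 50), rep(-2, 50))
  felPt <- freeEnergyLandscape(pt, gridSize = c(21, 21),
                               bandwidth = c(0.1, 0.1))
  mode <- which(felPt@freeEnergy == 0, arr.ind = TRUE)
  expect_equal(felPt@x[mode[1]], 1.5, tolerance = 0.05)
  expect_equal(felPt@y[mode[2]], -2, tolerance = 0.05)
  row <- felPt@freeEnergy[, mode[2]]
  expect_true(all(diff(row[seq_len(mode[1])]) <= 1e-9))
  expect_true(all(diff(row[mode[1]:length(row)]) >= -1e-9))
  ## weight scaling and sample duplication leave the surface unchanged
  felW <- freeEnergyLandscape(xy, gridSize = c(50, 50),
                              bandwidth = fel@bandwidth,
                              weights = rep(2, nrow(xy)))
  expect_equal(felW@freeEnergy, fel@freeEnergy, tolerance = 1e-12)
  felDup <- freeEnergyLandscape(rbind(xy, xy), gridSize = c(50, 50),
                                bandwidth = fel@bandwidth)
  expect_equal(felDup@freeEnergy, fel@freeEnergy, tolerance = 1e-9)
  expect_error(freeEnergyLandscape(xy, bandwidth = 0), "bandwidth")
})

test_that("landscape matches the closed-form Gaussian well", {
  set.seed(32)
  n <- 2e4
  xy <- cbind(rnorm(n), rnorm(n))
  fel <- freeEnergyLandscape(xy, gridSize = c(80, 80))
  r2 <- outer(fel@x^2, fel@y^2, "+")
  inside <- r2 <= 1.5^2
  err <- fel@freeEnergy[inside] - r2[inside] / 2
  expect_lt(max(abs(err)), 0.35)
})

test_that("autocorrelation-corrected errors detect duplication", {
  set.seed(41)
  x <- rnorm(1e4)
  e <- autocorrCorrectedError(x)
  expect_gte(e@inefficiency, 1)
  expect_lt(e@inefficiency, 1.2)
  expect_gte(e@se, sqrt(e@variance / length(x)) - 1e-12)
  ## element-wise duplication doubles the inefficiency but leaves the
  ## corrected error of the mean essentially unchanged
  dup <- rep(x, each = 2)
  ed <- autocorrCorrectedError(dup)
  expect_equal(ed@inefficiency, 2, tolerance = 0.25)
  expect_equal(ed@se, e@se, tolerance = 0.15)
  ## constant series: zero error, unit inefficiency
  ec <- autocorrCorrectedError(rep(3.2, 100))
  expect_equal(ec@se, 0)
  expect_equal(ec@inefficiency, 1)
  expect_error(autocorrCorrectedError(1:5), "at least 10")
})

test_that("histograms are normalised with sane error bars", {
  set.seed(51)
  x <- runif(2000)
  h <- histogramWithErrors(x, breaks = seq(0, 1, by = 0.1))
  expect_equal(sum(h$density * (h$upper - h$lower)), 1, tolerance = 1e-12)
  expect_true(all(abs(h$density - 1) < 3 * h$se + 1e-9))
  ## everything in one bin
  h1 <- histogramWithErrors(rep(0.25, 500), breaks = seq(0, 1, by = 0.5))
  expect_equal(h1$density, c(2, 0))
  expect_error(histogramWithErrors(numeric()), "empty")
})
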