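# Receptor topology, synthetic conformations and the screened-Coulomb
# interaction surrogate.

test_that("canonical topology has 3 arms x 2 generations of amine sites", {
  topo <- buildReceptorTopology()
  expect_length(siteLabels(topo), 6)
  expect_equal(sum(generationOf(topo) == 1L), 3)
  expect_equal(sum(generationOf(topo) == 2L), 3)
  ## (arm, generation) pairs partition the sites bijectively
  pairs <- paste(armOf(topo), generationOf(topo))
  expect_length(unique(pairs), 6)
  ## the cyclic rotation applied three times is the identity on sites
  rot <- armPermutations(topo, "cyclic")[[2]]
  expect_equal(rot[rot[rot]], seq_len(6))
  expect_length(armPermutations(topo, "full"), 6)
})

test_that("conformation generator is deterministic and bounded", {
  a <- generateConformation(0.0, seed = 42)
  b <- generateConformation(0.0, seed = 42)
  expect_identical(coords(a), coords(b))
  expect_error(generateConformation(-0.1, seed = 1), "openness")
  expect_error(generateConformation(1.3, seed = 1), "openness")
})

test_that("openness spans the closed-to-open Rg range", {
  rg0 <- radiusOfGyration(generateConformation(0, seed = 1, noise = 0))
  rg1 <- radiusOfGyration(generateConformation(1, seed = 1, noise = 0))
  expect_gt(rg1, rg0)
  expect_gt(rg0, 0.45)  # closed arrangement near 0.50 nm
  expect_lt(rg0, 0.55)
  expect_gt(rg1, 0.65)  # open arrangement beyond the open marker
  ## openness 1 beats openness 0 for every seed, noise included
  for (s in 1:5) {
    expect_gt(radiusOfGyration(generateConformation(1, seed = s)),
              radiusOfGyration(generateConformation(0, seed = s)))
  }
})

test_that("first-generation amines are clustered, second generation exposed", {
  conf <- generateConformation(0.5, seed = 7)
  topo <- conf@topology
  g1 <- coords(conf, paste0("N.", topo@sites[generationOf(topo) == 1L]))
  g2 <- coords(conf, paste0("N.", topo@sites[generationOf(topo) == 2L]))
  expect_lt(min(dist(g1)), min(dist(g2)))
})

test_that("generated conformations satisfy their own type invariants", {
  set.seed(99)
  for (i in 1:20) {
    conf <- generateConformation(runif(1), seed = sample.int(1e6, 1),
                                 noise = 0.02)
    expect_true(validObject(conf))
    ## ring exactly planar in the generator
    ring <- coords(conf, conf@topology@ringAtoms)
    expect_lt(max(abs(ring[, 3] - mean(ring[, 3]))), 1e-9)
    expect_gt(min(dist(coords(conf))), 0.05)
  }
})

test_that("ensembles reproduce the requested openness distribution", {
  ens <- generateEnsemble(900, "uniform", seed = 1)
  expect_equal(nFrames(ens), 900)
  ## point mass: all Rg equal within generator noise bounds
  pm <- generateEnsemble(10, 0.0, seed = 3)
  rg <- vapply(1:10, function(i) radiusOfGyration(getFrame(pm, i)),
               numeric(1))
  expect_lt(max(rg) - min(rg), 0.08)
  ## uniform mean within 3 standard errors of 0.5
  u <- generateEnsemble(1000, "uniform", seed = 5)
  se <- sqrt(1 / 12 / 1000)
  expect_lt(abs(mean(u@metadata$openness) - 0.5), 3 * se)
  ## the Rg support covers the closed/open markers
  rgAll <- vapply(seq_len(nFrames(u)),
                  function(i) radiusOfGyration(getFrame(u, i)), numeric(1))
  expect_lt(min(rgAll), 0.50)
  expect_gt(max(rgAll), 0.65)
})

test_that("screened-Coulomb surrogate matches its closed form", {
  ## frozen independent evaluation of
  ## C exp(-kappa r) / (eps r) / (kT ln10) at r = 0.5 nm, eps 80,
  ## I = 0.1 M, T = 298 K (kappa = 1.0300 nm^-1)
  expect_equal(screenedCoulombPK(0.5, 80, 0.1, 298), 0.363771063117,
               tolerance = 1e-9)
  ## monotone decay and positivity
  expect_gt(screenedCoulombPK(0.25), screenedCoulombPK(0.5))
  expect_gt(screenedCoulombPK(0.5), 0)
  ## 1/eps scaling at kappa = 0
  expect_equal(screenedCoulombPK(0.7, 40, 0),
               2 * screenedCoulombPK(0.7, 80, 0), tolerance = 1e-12)
})

test_that("interaction matrix is symmetric, zero-diagonal and distance-monotone", {
  conf <- generateConformation(0.5, seed = 11, noise = 0)
  W <- computeInteractionMatrix(conf, 80, 0.1, 298)
  expect_equal(max(abs(W - t(W))), 0)
  expect_equal(diag(W), setNames(rep(0, 6), siteLabels(conf)))
  expect_true(all(W >= 0))
  ## entries agree with the pairwise closed form on the same geometry
  N <- coords(conf, paste0("N.", siteLabels(conf)))
  D <- as.matrix(dist(N))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(W[i, j], screenedCoulombPK(D[i, j], 80, 0.1, 298),
                 tolerance = 1e-12)
  }
  ## strictly decreasing in distance
  ord <- order(D[upper.tri(D)])
  expect_true(all(diff(W[upper.tri(W)][ord]) <= 0))
})

test_that("unphysical amine geometries are rejected", {
  conf <- generateConformation(0.5, seed = 2, noise = 0)
  X <- coords(conf)
  X["N.a1.g1", ] <- X["N.a2.g1", ] + c(0.08, 0, 0)  # below the 0.1 nm floor
  bad <- conformationFromCoords(X)
  expect_error(computeInteractionMatrix(bad), "unphysical")
})

test_that("mannoside placement is deterministic and respects the restraint", {
  conf <- generateConformation(0.2, seed = 4, noise = 0)
  a <- placeMannoside(conf, poseSeed = 11, maxRingSeparation = 1.0)
  b <- placeMannoside(conf, poseSeed = 11, maxRingSeparation = 1.0)
  expect_identical(coords(a), coords(b))
  expect_true(hasLigand(a))
  lig <- atomTable(a)$label[atomTable(a)$mol == "ligand"]
  expect_length(lig, 23)  # 6 ring + O1 + 4x(O,H) + 8 tail
  expect_true(all(is.finite(coords(a, lig))))
  ## inside max_ring_separation 0.8 every ring pair is within the flat
  ## radius, so the restraint energy vanishes by construction
  c08 <- placeMannoside(conf, poseSeed = 12, maxRingSeparation = 0.8)
  expect_equal(restraintEnergy(c08), 0)
  sugarCtr <- colMeans(coords(c08, c(paste0("SC", 1:5), "SO5")))
  phenylCtr <- colMeans(coords(c08, conf@topology@ringAtoms))
  expect_lte(sqrt(sum((sugarCtr - phenylCtr)^2)), 0.8)
  expect_error(placeMannoside(a, poseSeed = 1), "already")
})
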