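# Hydrogen bonds, tail-ring distances and the restraint potential.

test_that("hydrogen bonds follow the geometric criterion", {
  ## ligand block far from the receptor, then one hydroxyl moved into a
  ## perfect donor geometry against a gen2 amine nitrogen
  L <- farLigandBlock(centre = c(0, 0, 3))
  conf0 <- fixtureWithLigand(L, openness = 0.3, seed = 1)
  expect_equal(nrow(detectHBonds(conf0)), 0)
  N <- coords(conf0, "N.a1.g2")[1, ]
  L1 <- L
  L1["O2", ] <- N + c(0.28, 0, 0)
  L1["HO2", ] <- N + c(0.18, 0, 0)   # linear D-H-A at 0.28 nm
  hb <- detectHBonds(fixtureWithLigand(L1, 0.3, 1))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor, "O2")
  expect_equal(hb$acceptor, "N.a1.g2")
  ## same arrangement at 0.50 nm: outside the default cutoff
  L2 <- L
  L2["O2", ] <- N + c(0.50, 0, 0)
  L2["HO2", ] <- N + c(0.40, 0, 0)
  expect_equal(nrow(detectHBonds(fixtureWithLigand(L2, 0.3, 1))), 0)
  ## bent geometry beyond 30 degrees is rejected even at short range
  L3 <- L
  L3["O2", ] <- N + c(0.28, 0, 0)
  L3["HO2", ] <- L3["O2", ] + 0.1 * c(-cos(50 * pi / 180),
                                      sin(50 * pi / 180), 0)
  expect_equal(nrow(detectHBonds(fixtureWithLigand(L3, 0.3, 1))), 0)
})

test_that("a constructed six-contact pose counts six hydrogen bonds", {
  rec <- generateConformation(0.3, seed = 1, noise = 0)
  X <- coords(rec)
  topo <- rec@topology
  L <- farLigandBlock(centre = c(0, 0, 3))
  ## four hydroxyl donors aimed at four amine nitrogens: outward along the
  ## arm for the exposed gen2 sites, downward for the buried gen1 site
  ## (the outward line of a gen1 amine runs into its pyrrolic nitrogen)
  targets <- c("N.a1.g2", "N.a2.g2", "N.a3.g2", "N.a1.g1")
  dirs <- rbind(X["N.a1.g2", ] / sqrt(sum(X["N.a1.g2", ]^2)),
                X["N.a2.g2", ] / sqrt(sum(X["N.a2.g2", ]^2)),
                X["N.a3.g2", ] / sqrt(sum(X["N.a3.g2", ]^2)),
                c(0, 0, -1))
  oxy <- c("O2", "O3", "O4", "O6")
  for (k in seq_along(targets)) {
    N <- X[targets[k], ]
    L[oxy[k], ] <- N + 0.28 * dirs[k, ]
    L[paste0("H", oxy[k]), ] <- N + 0.18 * dirs[k, ]
  }
  ## two receptor amine donors aimed along their own N-H lines
  for (spec in list(c("N.a2.g1", "H.a2.g1", "SO5"),
                    c("N.a3.g1", "H.a3.g1", "O1"))) {
    N <- X[spec[1], ]; H <- X[spec[2], ]
    t <- (H - N) / sqrt(sum((H - N)^2))
    L[spec[3], ] <- N + 0.28 * t
  }
  conf <- fixtureWithLigand(L, 0.3, 1)
  expect_equal(nrow(detectHBonds(conf)), 6)
  ## rigid motion leaves the count unchanged
  expect_equal(nrow(detectHBonds(rigidCopy(conf, 5))), 6)
})

test_that("hydrogen-bond counting is bounded by the declared donor-acceptor pairs", {
  conf <- placeMannoside(generateConformation(0.2, seed = 4, noise = 0),
                         poseSeed = 11)
  loose <- HBondCriterion(distanceCutoff = 1e3, angleCutoff = 90)
  nLoose <- nrow(detectHBonds(conf, loose))
  ## receptor donors (6 amine + 3 pyrrole) x ligand acceptors (6), plus
  ## ligand donors (4) x receptor acceptors (6)
  expect_lte(nLoose, 9 * 6 + 4 * 6)
  expect_gte(nLoose, nrow(detectHBonds(conf)))
  ## a declared donor without its hydrogen is an input error
  X <- coords(conf)
  bad <- conformationFromCoords(X[rownames(X) != "HO2", ])
  expect_error(detectHBonds(bad), "missing hydrogen")
})

test_that("tail-ring distance is the centroid distance of the last 4 carbons", {
  rec <- generateConformation(0.3, seed = 1, noise = 0)
  ringCtr <- colMeans(coords(rec, rec@topology@ringAtoms))
  L <- farLigandBlock(centre = c(0, 0, 3))
  ## place the four terminal carbons symmetrically about a point 1.0 nm
  ## from the ring centroid along x
  ctr <- ringCtr + c(1.0, 0, 0)
  off <- rbind(c(0.08, 0, 0), c(-0.08, 0, 0), c(0, 0.08, 0), c(0, -0.08, 0))
  for (i in 1:4) L[paste0("CT", 4 + i), ] <- ctr + off[i, ]
  conf <- fixtureWithLigand(L, 0.3, 1)
  expect_equal(tailRingDistance(conf), 1.0, tolerance = 1e-12)
  expect_equal(tailRingDistance(rigidCopy(conf, 2)), 1.0, tolerance = 1e-9)
  ## coincident centroids give zero (carbons straddle the ring plane to
  ## keep clear of the ring atoms themselves)
  offZ <- rbind(c(0, 0, 0.3), c(0, 0, -0.3), c(0.3, 0, 0), c(-0.3, 0, 0))
  for (i in 1:4) L[paste0("CT", 4 + i), ] <- ringCtr + offZ[i, ]
  expect_equal(tailRingDistance(fixtureWithLigand(L, 0.3, 1)), 0,
               tolerance = 1e-12)
  expect_error(tailRingDistance(rec), "ligand")
})

test_that("restraint potential matches its piecewise closed form", {
  spec <- RestraintSpec(k = 100, r0 = 1.0, r1 = 1.2)
  expect_equal(restraintPotential(0.7, spec), 0)
  expect_equal(restraintPotential(1.0, spec), 0)
  ## quadratic branch: 0.5 * 100 * 0.2^2
  expect_equal(restraintPotential(1.2, spec), 2.0, tolerance = 1e-12)
  ## linear branch: 2.0 + 100 * 0.2 * 0.2
  expect_equal(restraintPotential(1.4, spec), 6.0, tolerance = 1e-12)
  ## value and slope continuity at both switch points
  eps <- 1e-7
  for (r in c(1.0, 1.2)) {
    expect_equal(restraintPotential(r + eps, spec),
                 restraintPotential(r - eps, spec), tolerance = 1e-4)
    dLeft <- (restraintPotential(r, spec) -
                restraintPotential(r - eps, spec)) / eps
    dRight <- (restraintPotential(r + eps, spec) -
                 restraintPotential(r, spec)) / eps
    expect_equal(dLeft, dRight, tolerance = 1e-4)
  }
  ## monotone non-decreasing
  d <- seq(0.5, 2, by = 0.01)
  expect_true(all(diff(restraintPotential(d, spec)) >= 0))
})

test_that("ring-ring restraint energy sums the 36 pair penalties", {
  conf <- placeMannoside(generateConformation(0.6, seed = 7, noise = 0),
                         poseSeed = 3, pose = "loose")
  A <- coords(conf, conf@topology@ringAtoms)
  B <- coords(conf, c(paste0("SC", 1:5), "SO5"))
  d <- as.numeric(sqrt(outer(rowSums(A^2), rowSums(B^2), "+") -
                         2 * A %*% t(B)))
  spec <- RestraintSpec()
  expect_equal(restraintEnergy(conf, spec),
               sum(restraintPotential(d, spec)), tolerance = 1e-9)
  expect_equal(restraintEnergy(conf, spec, variant = "min"),
               restraintPotential(min(d), spec), tolerance = 1e-9)
  ## zero iff every pair is inside the flat radius
  near <- placeMannoside(generateConformation(0.2, seed = 4, noise = 0),
                         poseSeed = 12, maxRingSeparation = 0.8)
  expect_equal(restraintEnergy(near, spec), 0)
})

test_that("pose modes produce the expected interaction contrasts", {
  ## head-bound frames are hydrogen-bond rich; tail-stacked frames sit at
  ## small tail-ring distances
  mkEns <- function(pose, n = 15) {
    confs <- lapply(seq_len(n), function(i)
      placeMannoside(generateConformation(0.15, seed = 100 + i,
                                          noise = 0.01),
                     poseSeed = 200 + i, pose = pose))
    new("EnsembleRecord", template = confs[[1]],
        coordsList = lapply(confs, coords),
        states = list(), frames = seq_len(n), metadata = list(pose = pose))
  }
  head <- interactionHistograms(mkEns("head"))
  tail <- interactionHistograms(mkEns("tail"))
  massGe2 <- function(res) mean(res$perFrame$hbond_count >= 2)
  expect_gt(massGe2(head), massGe2(tail))
  expect_lt(median(tail$perFrame$tail_ring_distance),
            median(head$perFrame$tail_ring_distance))
  ## an ensemble of identical frames collapses to single-bin histograms
  one <- placeMannoside(generateConformation(0.15, seed = 100, noise = 0),
                        poseSeed = 201, pose = "tail")
  ens1 <- new("EnsembleRecord", template = one,
              coordsList = rep(list(coords(one)), 12), states = list(),
              frames = 1:12, metadata = list())
  res1 <- interactionHistograms(ens1)
  expect_equal(sum(res1$hbondHistogram$count > 0), 1)
  expect_equal(sum(res1$distanceHistogram$count > 0), 1)
})
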