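# Independent oracles and fixture builders used across the suite.

## Total variation distance between two distributions on the same support.
tvd <- function(p, q) sum(abs(p - q)) / 2

## Quaternion (Horn) superposition: RMSD after the optimal proper rotation
## and translation.  Independent of the package's SVD-based Kabsch fit.
hornRMSD <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- t(Xc) %*% Yc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[3, 1] + S[1, 3]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max(0, (sum(Xc^2) + sum(Yc^2) - 2 * lmax) / nrow(X)))
}

## Brute-force orbit enumeration of the 64 microstates under all six arm
## permutations (site order: gen1 on arms 1-3, then gen2 on arms 1-3).
orbitOracle <- function() {
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2),
                c(1, 3, 2), c(3, 2, 1), c(2, 1, 3))
  states <- as.matrix(expand.grid(rep(list(0:1), 6)))
  dimnames(states) <- NULL
  reps <- apply(states, 1, function(s)
    min(vapply(perms, function(p) paste(c(s[p], s[3 + p]), collapse = ""),
               character(1))))
  list(states = states, reps = reps, n = rowSums(states))
}

## Random rigid transform of a labelled coordinate matrix.
applyRandomRigid <- function(X, seed) {
  set.seed(seed)
  ang <- runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3)
  Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                 sin(ang[2]), 0, cos(ang[2])), 3)
  Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0,
                 -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3)
  R <- Rz %*% Ry %*% Rx
  tr <- runif(3, -2, 2)
  sweep(X %*% t(R), 2, tr, "+")
}

rigidCopy <- function(conf, seed) {
  X <- applyRandomRigid(coords(conf), seed)
  rownames(X) <- rownames(coords(conf))
  conformationFromCoords(X, metadata = conf@metadata)
}

## Hand-built receptor + ligand fixture: the receptor from the generator,
## the ligand block positioned explicitly by the caller.
fixtureWithLigand <- function(ligandCoords, openness = 0.3, seed = 1) {
  rec <- generateConformation(openness, seed, noise = 0)
  X <- rbind(coords(rec), ligandCoords)
  conformationFromCoords(X)
}

## Default far-away ligand block (no receptor contacts): a compact, legal
## ligand around `centre`, useful as a base for hand-edited fixtures.
farLigandBlock <- function(centre = c(0, 0, 3)) {
  hex <- t(vapply(0:5, function(i)
    centre + 0.145 * c(cos(i * pi / 3), sin(i * pi / 3), 0), numeric(3)))
  O <- t(vapply(1:4, function(k) {
    v <- hex[k + 1, ] - centre
    hex[k + 1, ] + 0.13 * v / sqrt(sum(v^2))
  }, numeric(3)))
  H <- O + 0.1 * t(vapply(1:4, function(k) {
    v <- O[k, ] - centre
    v / sqrt(sum(v^2))
  }, numeric(3)))
  O1 <- hex[1, ] + c(0, 0, 0.13)
  tail <- t(vapply(0:7, function(i)
    O1 + c(0, 0, 0.13 + i * 0.127) + c(0.04 * (i %% 2), 0, 0), numeric(3)))
  L <- rbind(hex, O1, O[1, ], H[1, ], O[2, ], H[2, ], O[3, ], H[3, ],
             O[4, ], H[4, ], tail)
  rownames(L) <- c(paste0("SC", 1:5), "SO5", "O1", "O2", "HO2", "O3", "HO3",
                   "O4", "HO4", "O6", "HO6", paste0("CT", 1:8))
  L
}
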