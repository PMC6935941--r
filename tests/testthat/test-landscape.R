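test_that("edge weights follow the exponential pseudotime rule", {
  tau <- c(0, 0.1, 0.1)
  coords <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  cs <- makeCS(abs(coords) + 1, reduced = coords)
  ord <- manualOrdering(cellIds(cs), tau)
  g <- buildWeightGraph(ord, cs, chi = 30, kNeighbors = 2, W0 = 2)
  w <- g@weight
  # equal pseudotimes: weight = W0
  same <- g@from != 1L & g@to != 1L
  expect_equal(w[same], rep(2, sum(same)))
  # forward by 0.1 at chi = 30: weight = W0 * e^3
  fwd <- g@from == 1L
  expect_equal(w[fwd], rep(2 * exp(3), sum(fwd)), tolerance = 1e-12)
  bwd <- g@to == 1L
  expect_equal(w[bwd], rep(2 * exp(-3), sum(bwd)), tolerance = 1e-12)
})

test_that("graph support matches a brute-force kNN enumeration", {
  set.seed(31)
  coords <- matrix(rnorm(10), 5, 2)
  cs <- makeCS(abs(coords) + 1, reduced = coords)
  ord <- manualOrdering(cellIds(cs), seq(0, 1, length.out = 5))
  g <- buildWeightGraph(ord, cs, kNeighbors = 2)
  # brute-force: union of each cell's 2 nearest neighbors, symmetrized
  expectPairs <- character(0)
  for (i in 1:5) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2)); d[i] <- Inf
    for (j in order(d)[1:2])
      expectPairs <- c(expectPairs, paste(i, j), paste(j, i))
  }
  gotPairs <- paste(g@from, g@to)
  expect_setequal(gotPairs, unique(expectPairs))
  expect_error(buildWeightGraph(ord, cs, kNeighbors = 5), "smaller")
})

test_that("conditional probabilities are W0-invariant row distributions", {
  set.seed(32)
  coords <- matrix(rnorm(60), 30, 2)
  cs <- makeCS(abs(coords) + 1, reduced = coords)
  ord <- manualOrdering(cellIds(cs), runif(30))
  g1 <- conditionalProbabilities(buildWeightGraph(ord, cs,
                                                  kNeighbors = 4))
  rows <- rowsum(g1@conditional, g1@from)
  expect_equal(unname(rows[, 1]), rep(1, nrow(rows)), tolerance = 1e-12)
  # doubling W0 leaves conditionals unchanged to the last bit
  g2 <- conditionalProbabilities(buildWeightGraph(ord, cs,
                                                  kNeighbors = 4,
                                                  W0 = 2))
  expect_identical(g1@conditional, g2@conditional)
  # two equal-weight out-edges: 0.5 each
  csT <- makeCS(matrix(c(0, 1, 2), 3, 1) + 1,
                reduced = matrix(c(0, 1, 2), 3, 1))
  ordT <- manualOrdering(cellIds(csT), c(0.5, 0.5, 0.5))
  gT <- conditionalProbabilities(buildWeightGraph(ordT, csT,
                                                  kNeighbors = 2))
  expect_equal(gT@conditional[gT@from == 2L], c(0.5, 0.5))
})

test_that("stationary distribution solves the teleported fixed point", {
  # complete graph with all pseudotimes equal: uniform stationary
  set.seed(33)
  coords <- matrix(rnorm(40), 20, 2)
  cs <- makeCS(abs(coords) + 1, reduced = coords)
  ord <- manualOrdering(cellIds(cs), rep(0.4, 20))
  g <- solveWalk(ord, cs, k = 19)
  expect_equal(stationaryProbs(g), rep(1 / 20, 20), tolerance = 1e-9)

  # hand-sized graphs match the dense linear-system oracle
  for (seed in 1:5) {
    set.seed(seed)
    m <- sample(10:60, 1)
    coords <- matrix(rnorm(m * 2), m, 2)
    cs <- makeCS(abs(coords) + 1, reduced = coords)
    ord <- manualOrdering(cellIds(cs), runif(m))
    g <- solveWalk(ord, cs, k = 4)
    expect_equal(stationaryProbs(g), denseStationary(g, 0.01),
                 tolerance = 1e-8)
    expect_equal(sum(stationaryProbs(g)), 1, tolerance = 1e-9)
    expect_true(all(stationaryProbs(g) > 0))
  }
})

test_that("stationary p is invariant to W0 and uniform pseudotime shift", {
  set.seed(34)
  m <- 40
  coords <- matrix(rnorm(m * 2), m, 2)
  cs <- makeCS(abs(coords) + 1, reduced = coords)
  tau <- runif(m, 0, 0.5)
  base <- solveWalk(manualOrdering(cellIds(cs), tau), cs, k = 5)
  # W0 = 7
  g2 <- buildWeightGraph(manualOrdering(cellIds(cs), tau), cs,
                         kNeighbors = 5, W0 = 7)
  g2 <- stationaryDistribution(conditionalProbabilities(g2))
  expect_equal(stationaryProbs(g2), stationaryProbs(base),
               tolerance = 1e-12)
  # tau + 0.3 (manualOrdering must not rescale: range stays in [0,1])
  g3 <- solveWalk(manualOrdering(cellIds(cs), tau + 0.3), cs, k = 5)
  expect_equal(stationaryProbs(g3), stationaryProbs(base),
               tolerance = 1e-10)
})

test_that("cell potentials are the negative log stationary probabilities", {
  set.seed(35)
  coords <- matrix(rnorm(30), 15, 2)
  cs <- makeCS(abs(coords) + 1, reduced = coords)
  ord <- manualOrdering(cellIds(cs), rep(0.2, 15))
  g <- solveWalk(ord, cs, k = 14)
  E <- cellPotentials(g)
  expect_equal(unname(E), rep(log(15), 15), tolerance = 1e-8)
  # monotone: higher visit probability, lower potential
  g2 <- solveWalk(manualOrdering(cellIds(cs), runif(15)), cs, k = 4)
  p <- stationaryProbs(g2); E2 <- cellPotentials(g2)
  expect_equal(order(p), order(-E2))
})

test_that("the landscape surface interpolates and smooths correctly", {
  set.seed(36)
  m <- 80
  emb <- rbind(matrix(rnorm(m, sd = 0.4), m / 2, 2),
               matrix(rnorm(m, mean = 4, sd = 0.4), m / 2, 2))
  cs <- makeCS(cbind(abs(emb) + 1, runif(m)))
  E <- c(rep(1, m / 2), rep(5, m / 2)) + runif(m, 0, 0.1)
  surf0 <- buildLandscapeSurface(E, cs, method = "custom",
                                 embedding = emb, gridResolution = 32,
                                 smoothingBandwidth = 0)
  # bandwidth 0: surface equals the nearest-neighbor interpolant
  expect_identical(surf0@values, surf0@nnValues)
  # a grid point exactly on an embedded cell takes that cell's E
  gx <- surf0@gridX; gy <- surf0@gridY
  i <- which.min(abs(gx - emb[1, 1])); j <- which.min(abs(gy - emb[1, 2]))
  nn <- which.min((emb[, 1] - gx[i])^2 + (emb[, 2] - gy[j])^2)
  expect_equal(surf0@values[j, i], E[nn])

  surf <- buildLandscapeSurface(E, cs, method = "custom",
                                embedding = emb, gridResolution = 32,
                                smoothingBandwidth = 1)
  # smoothing preserves the two-basin structure: the deepest grid value
  # sits in the low-potential cluster's corner of the grid
  low <- which(surf@values == min(surf@values), arr.ind = TRUE)[1, ]
  expect_lt(surf@gridX[low[2]], 2)
  expect_lt(surf@gridY[low[1]], 2)

  expect_error(buildLandscapeSurface(E, cs, method = "custom",
                                     embedding = cbind(emb[, 1], 0),
                                     gridResolution = 32),
               "degenerate")
})

test_that("pseudo-potential and landscape potential can disagree in sign", {
  # early-dense linear data: early cells are denser (lower
  # pseudo-potential) but the forward-biased walk accumulates late
  # (early cells get higher landscape potential)
  sim <- simulateBranchingTrajectory(800, "linear",
                                     densityProfile = "early-dense",
                                     seed = 7)
  bb <- runBackbone(sim)
  g <- solveWalk(bb$ordering, bb$cs)
  E <- cellPotentials(g)
  tr <- sim$truth$cells
  early <- tr$t <= quantile(tr$t, 1 / 3)
  late <- tr$t >= quantile(tr$t, 2 / 3)
  expect_lt(mean(pseudoPotential(bb$field)[early]),
            mean(pseudoPotential(bb$field)[late]))
  expect_gt(mean(E[early]), mean(E[late]))
})
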