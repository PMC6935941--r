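test_that("cell types mirror the chain structure of the backbone", {
  simL <- simulateBranchingTrajectory(800, "linear", seed = 5)
  bbL <- runBackbone(simL)
  aL <- assignCellTypes(bbL$ordering)
  expect_equal(aL@nTypes, 1L)
  expect_true(all(cellTypes(aL) == 1L))

  simY <- simulateBranchingTrajectory(1000, "bifurcation", seed = 3)
  bbY <- runBackbone(simY)
  aY <- assignCellTypes(bbY$ordering)
  expect_equal(aY@nTypes, 3L)  # trunk + two arms
  expect_setequal(unique(cellTypes(aY)), 1:3)
})

test_that("subtype wells split multimodal potential profiles", {
  # a hand-built potential profile over one branch: two basins with a
  # barrier of 1 natural-log unit at tau = 0.5
  m <- 200
  tau <- seq(0, 1, length.out = m)
  pot <- 2 - cos(2 * pi * tau)  # minima at 0 and 1, barrier at 0.5
  ord <- manualOrdering(sprintf("c%03d", 1:m), tau)
  asg <- new("CellTypeAssignment", typeId = rep(1L, m),
             subtypeId = rep(NA_integer_, m), nTypes = 1L)
  out <- detectSubtypeWells(asg, pot, ord)
  expect_equal(length(unique(cellSubtypes(out))), 2L)
  # the basin boundary sits at the barrier
  boundary <- max(tau[cellSubtypes(out) == 1])
  expect_lt(abs(boundary - 0.5), 0.05)

  # monotone profile: a single subtype
  out2 <- detectSubtypeWells(asg, 3 * tau, ord)
  expect_equal(unique(cellSubtypes(out2)), 1L)

  # infinite barrier threshold: always one subtype
  out3 <- detectSubtypeWells(asg, pot, ord, barrierMin = Inf)
  expect_equal(unique(cellSubtypes(out3)), 1L)

  # undersized branches warn and collapse
  asgS <- new("CellTypeAssignment", typeId = rep(1L, 5),
              subtypeId = rep(NA_integer_, 5), nTypes = 1L)
  expect_warning(
    out4 <- detectSubtypeWells(asgS, pot[1:5],
                               manualOrdering(sprintf("c%d", 1:5),
                                              tau[1:5])),
    "fewer than 10")
  expect_equal(unique(cellSubtypes(out4)), 1L)
})

test_that("link visit rates conserve total probability", {
  set.seed(41)
  m <- 50
  coords <- matrix(rnorm(m * 2), m, 2)
  cs <- makeCS(abs(coords) + 1, reduced = coords)
  g <- solveWalk(manualOrdering(cellIds(cs), runif(m)), cs, k = 5)
  rates <- linkVisitRates(g)
  expect_equal(sum(rates$q), 1, tolerance = 1e-9)
  # hand product on a two-cell graph
  cs2 <- makeCS(matrix(c(1, 2), 2, 1), reduced = matrix(c(0, 1), 2, 1))
  g2 <- solveWalk(manualOrdering(cellIds(cs2), c(0.5, 0.5)), cs2, k = 1)
  r2 <- linkVisitRates(g2)
  expect_equal(sort(r2$q), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("type dynamics aggregate link rates consistently", {
  # toy 2-type system with hand-set stationary and conditionals
  g <- new("TransitionGraph",
           from = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L),
           to   = c(2L, 3L, 1L, 3L, 1L, 4L, 3L, 2L),
           weight = rep(1, 8),
           conditional = c(0.7, 0.3, 0.6, 0.4, 0.5, 0.5, 0.9, 0.1),
           stationary = c(0.1, 0.2, 0.3, 0.4), nCells = 4L,
           W0 = 1, chi = 30, epsilon = 0.01, kNeighbors = 2L)
  rates <- linkVisitRates(g)
  asg <- new("CellTypeAssignment", typeId = c(1L, 1L, 2L, 2L),
             subtypeId = rep(NA_integer_, 4), nTypes = 2L)
  dyn <- cellTypeDynamics(rates, asg)
  # hand enumeration: q12 = p1*p(1->3) + p2*p(2->3) = 0.03 + 0.08
  expect_equal(transitionMatrix(dyn)[1, 2], 0.1 * 0.3 + 0.2 * 0.4)
  # q21 = p3*p(3->1) + p4*p(4->2) = 0.15 + 0.04
  expect_equal(transitionMatrix(dyn)[2, 1], 0.3 * 0.5 + 0.4 * 0.1)
  expect_equal(exitProbs(dyn),
               c(transitionMatrix(dyn)[1, 2], transitionMatrix(dyn)[2, 1]),
               tolerance = 1e-12)
  expect_equal(fateProbs(dyn), 1 - exitProbs(dyn))
  # global conservation: internal flux + exits = 1
  expect_equal(sum(dyn@internalFlux) + sum(exitProbs(dyn)), 1,
               tolerance = 1e-9)

  # the printed (uncorrected) index-set variant differs by construction
  dynP <- cellTypeDynamics(rates, asg, printedIndexSet = TRUE)
  expect_false(isTRUE(all.equal(transitionMatrix(dynP),
                                transitionMatrix(dyn))))
})

test_that("a single type keeps the walker: exit 0, fate 1", {
  set.seed(42)
  m <- 30
  coords <- matrix(rnorm(m * 2), m, 2)
  cs <- makeCS(abs(coords) + 1, reduced = coords)
  g <- solveWalk(manualOrdering(cellIds(cs), runif(m)), cs, k = 4)
  asg <- new("CellTypeAssignment", typeId = rep(1L, m),
             subtypeId = rep(NA_integer_, m), nTypes = 1L)
  dyn <- cellTypeDynamics(linkVisitRates(g), asg)
  expect_equal(exitProbs(dyn), 0)
  expect_equal(fateProbs(dyn), 1)
})

test_that("forward transitions beat reverse on a forward-gradient walk", {
  sim <- simulateBranchingTrajectory(1000, "bifurcation", seed = 11)
  bb <- runBackbone(sim)
  g <- solveWalk(bb$ordering, bb$cs, chi = 30)
  asg <- assignCellTypes(bb$ordering)
  dyn <- cellTypeDynamics(linkVisitRates(g), asg)
  q <- transitionMatrix(dyn)
  # type 1 is the root chain (trunk); 2 and 3 are the arms
  expect_gt(q[1, 2], q[2, 1])
  expect_gt(q[1, 3], q[3, 1])
})
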