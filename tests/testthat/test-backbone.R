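test_that("adaptive step returns the smallest feasible ring radius", {
  set.seed(21)
  # uniform disc of cells
  ang <- runif(400, 0, 2 * pi); rad <- sqrt(runif(400)) * 10
  coords <- cbind(rad * cos(ang), rad * sin(ang))
  cs <- makeCS(abs(coords) + 1, reduced = coords)
  ctx <- new("DistanceContext", sigma = 0.5)
  r <- adaptiveStep(c(0, 0), cs, ctx, minRingCells = 10,
                    baseRadius = 1.5, halfWidth = 0.5)
  expect_false(is.na(r))
  d <- sqrt(rowSums(coords^2))
  expect_gte(sum(abs(d - r) <= 0.5), 10)
  # exhaustive scan: r is within one grid step of the minimal feasible
  grid <- 1.5 * 1.1^(0:60)
  feasible <- grid[vapply(grid, function(g)
    sum(abs(d - g) <= 0.5) >= 10, logical(1))]
  expect_lte(r, min(feasible) * 1.1 + 1e-12)

  # center far outside the cloud: annuli never fill -> boundary signal
  rFar <- adaptiveStep(c(1e4, 1e4), cs, ctx, minRingCells = 10,
                       baseRadius = 1.5, halfWidth = 0.5)
  expect_true(is.na(rFar))

  # two cells at distance 10, minRingCells = 2 -> r reaches ~10
  cs2 <- makeCS(matrix(c(0, 0, 10, 0, 10.5, 0), 3, 2, byrow = TRUE))
  r2 <- adaptiveStep(c(0, 0), cs2, new("DistanceContext", sigma = 1),
                     minRingCells = 2, baseRadius = 3, halfWidth = 1)
  expect_true(abs(r2 - 10) <= 1)
})

test_that("wells on a ring are found per dense cluster", {
  set.seed(22)
  # two dense clusters a quarter-turn apart on a radius-5 ring
  n1 <- 60; n2 <- 60
  th <- c(rnorm(n1, 0, 0.08), rnorm(n2, pi / 2, 0.08))
  rr <- 5 + rnorm(n1 + n2, 0, 0.1)
  coords <- rbind(cbind(rr * cos(th), rr * sin(th)), c(0, 0))
  cs <- makeCS(abs(coords) + 1, reduced = coords)
  ctx <- new("DistanceContext", sigma = 0.5)
  field <- computePseudoPotential(cs, ctx)
  wells <- findWellsOnRing(c(0, 0), 5, cs, field, halfWidth = 0.5)
  expect_equal(length(wells), 2L)
  angles <- atan2(coords[wells, 2], coords[wells, 1])
  expect_equal(sort(round(angles / (pi / 2))), c(0, 1))
  # wells sorted by ascending pseudo-potential
  expect_true(!is.unsorted(field@eTilde[wells]))

  # empty annulus
  expect_length(findWellsOnRing(c(100, 100), 5, cs, field,
                                halfWidth = 0.5), 0L)
})

test_that("uniform rings yield at most one well", {
  set.seed(23)
  for (rep in 1:5) {
    # dense uniform sampling: spacing well below the link cutoff
    th <- runif(800, 0, 2 * pi)
    rr <- 5 + rnorm(800, 0, 0.1)
    coords <- cbind(rr * cos(th), rr * sin(th))
    cs <- makeCS(abs(coords) + 1, reduced = coords)
    ctx <- new("DistanceContext", sigma = 0.5)
    field <- computePseudoPotential(cs, ctx)
    wells <- findWellsOnRing(c(0, 0), 5, cs, field, halfWidth = 0.5)
    expect_lte(length(wells), 1L)
  }
})

test_that("tree growth recovers the generator topology", {
  simY <- simulateBranchingTrajectory(1000, "bifurcation", seed = 3)
  bbY <- runBackbone(simY)
  degY <- nodeDeg(bbY$tree)
  expect_equal(sum(degY >= 3), 1L)
  expect_equal(max(degY), 3L)
  expect_equal(sum(degY == 1), 3L)

  simL <- simulateBranchingTrajectory(1000, "linear", seed = 3)
  bbL <- runBackbone(simL)
  expect_equal(sum(nodeDeg(bbL$tree) >= 3), 0L)

  # trees are structurally valid
  for (tree in list(bbY$tree, bbL$tree)) {
    expect_equal(nrow(treeEdges(tree)),
                 length(tree@nodeCells) - 1L)
    expect_true(validObject(tree))
  }
})

test_that("a cluster tight on the kernel scale gives a single-node tree", {
  set.seed(24)
  coords <- matrix(rnorm(200 * 2, sd = 0.1), 200, 2)
  cs <- makeCS(abs(coords) + 1, reduced = coords)
  # the cluster has no structure at the search scale: rings never fill
  ctx <- new("DistanceContext", sigma = 0.5)
  field <- computePseudoPotential(cs, ctx)
  tree <- growBackboneTree(cs, field)
  expect_equal(length(tree@nodeCells), 1L)
  expect_equal(nrow(treeEdges(tree)), 0L)
})

test_that("too few cells are refused", {
  set.seed(25)
  coords <- matrix(rnorm(50 * 2), 50, 2)
  cs <- makeCS(abs(coords), reduced = coords)
  ctx <- deriveSigma(cs, 0.05)
  field <- computePseudoPotential(cs, ctx)
  expect_error(growBackboneTree(cs, field), "unreliab")
})

test_that("refinement with zero subdivisions is the identity", {
  sim <- simulateBranchingTrajectory(600, "linear", seed = 6)
  bb <- runBackbone(sim)
  expect_identical(refineBackboneTree(bb$tree, bb$field, bb$cs, 0),
                   bb$tree)
  # refinement preserves topology (leaf count, branch count)
  ref <- refineBackboneTree(bb$tree, bb$field, bb$cs, 2)
  expect_equal(sum(nodeDeg(ref) >= 3), sum(nodeDeg(bb$tree) >= 3))
  expect_equal(sum(nodeDeg(ref) == 1), sum(nodeDeg(bb$tree) == 1))
  expect_equal(nrow(treeEdges(ref)), length(ref@nodeCells) - 1L)
})

test_that("refinement pulls edges toward the data ridge", {
  # a curved arc with a deliberately coarse two-node tree spanning it
  set.seed(26)
  th <- runif(400, 0, pi / 2)
  coords <- cbind(10 * cos(th), 10 * sin(th)) +
    matrix(rnorm(800, sd = 0.15), 400, 2)
  cs <- makeCS(abs(coords) + 20, reduced = coords)
  ctx <- deriveSigma(cs, 0.05)
  field <- computePseudoPotential(cs, ctx)
  a <- which.min(abs(th)); b <- which.min(abs(th - pi / 2))
  tree <- new("BackboneTree", nodeCells = as.integer(c(a, b)),
              nodeCoords = coords[c(a, b), ], rootNode = 1L,
              edges = matrix(c(1L, 2L), 1, 2), params = list())
  ref <- refineBackboneTree(tree, field, cs, nSubdivisions = 4,
                            halfWidth = 2)
  ordCoarse <- projectCells(tree, cs)
  ordRef <- projectCells(ref, cs)
  expect_lt(mean(ordRef@projectionDist), mean(ordCoarse@projectionDist))
})

test_that("projection, pseudotime and branch labels behave as specified", {
  sim <- simulateBranchingTrajectory(1000, "bifurcation", seed = 3)
  bb <- runBackbone(sim)
  ord <- bb$ordering
  tau <- pseudotime(ord)
  expect_gte(min(tau), 0)
  expect_equal(max(tau), 1)

  # a cell coincident with a tree node projects at distance 0
  nodeCell <- bb$tree@nodeCells[5]
  expect_lt(ord@projectionDist[nodeCell], 1e-10)

  # root cell (the node chosen as root) has pseudotime 0
  rootCell <- bb$tree@nodeCells[ord@rootNode]
  expect_equal(unname(tau[rootCell]), 0)

  # three chains = three branch labels on a single bifurcation
  expect_equal(length(unique(branchIds(ord))), 3L)

  # pseudotime orders cells within every true branch
  tr <- sim$truth$cells
  for (b in unique(tr$branch)) {
    sel <- tr$branch == b
    expect_gte(cor(tau[sel], tr$t[sel], method = "spearman"), 0.95)
  }
})

test_that("singleton trees give the degenerate flagged ordering", {
  set.seed(27)
  coords <- matrix(rnorm(150 * 2, sd = 0.05), 150, 2)
  cs <- makeCS(abs(coords) + 1, reduced = coords)
  ctx <- new("DistanceContext", sigma = 0.4)
  field <- computePseudoPotential(cs, ctx)
  tree <- growBackboneTree(cs, field)
  expect_warning(ord <- projectCells(tree, cs), "degenerate")
  expect_true(all(pseudotime(ord) == 0))
})

test_that("the pipeline is invariant to cell-order permutation", {
  sim <- simulateBranchingTrajectory(600, "bifurcation", seed = 8)
  cs <- preprocessCells(sim$cs, logTransform = FALSE, reduceTo = 10)
  ctx <- deriveSigma(cs)
  field <- computePseudoPotential(cs, ctx)
  tree <- growBackboneTree(cs, field)

  set.seed(99); perm <- sample(nCells(cs))
  vP <- exprValues(sim$cs)[perm, ]
  csP <- preprocessCells(CellStateSet(vP), logTransform = FALSE,
                         reduceTo = 10)
  ctxP <- deriveSigma(csP)
  expect_equal(kernelSigma(ctxP), kernelSigma(ctx), tolerance = 1e-9)
  fieldP <- computePseudoPotential(csP, ctxP)
  expect_equal(unname(localDensity(fieldP)),
               unname(localDensity(field)[perm]), tolerance = 1e-9)
  treeP <- growBackboneTree(csP, fieldP)
  # identical node set up to the cell relabeling
  expect_setequal(cellIds(csP)[treeP@nodeCells],
                  cellIds(cs)[tree@nodeCells])
  expect_equal(nrow(treeEdges(treeP)), nrow(treeEdges(tree)))
})
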