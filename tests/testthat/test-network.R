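test_that("pseudotime windows tile, overlap, and merge as specified", {
  m <- 1000
  ord <- manualOrdering(sprintf("c%04d", 1:m),
                        seq(0, 1, length.out = m))
  w <- makePseudotimeWindows(ord, nWindows = 10, overlapFraction = 0.5)
  expect_equal(length(w), 10L)
  # consecutive windows share about half their cells
  shared <- length(intersect(w[[1]]$cells, w[[2]]$cells))
  expect_equal(shared / length(w[[1]]$cells), 0.5, tolerance = 0.06)
  # coverage: every cell is in some window
  expect_setequal(unique(unlist(lapply(w, `[[`, "cells"))), 1:m)

  # all mass at one point: a single window with every cell
  ord2 <- manualOrdering(sprintf("c%04d", 1:m), rep(0.5, m))
  w2 <- makePseudotimeWindows(ord2, nWindows = 10,
                              overlapFraction = 0.5)
  expect_equal(length(w2), 1L)
  expect_length(w2[[1]]$cells, m)

  expect_error(makePseudotimeWindows(
    manualOrdering("c1", 0.5), nWindows = 5), "too few cells")
})

test_that("per-branch windows never mix post-branch branches", {
  sim <- simulateBranchingTrajectory(1000, "bifurcation", seed = 3)
  bb <- runBackbone(sim)
  w <- makePseudotimeWindows(bb$ordering, nWindows = 8,
                             overlapFraction = 0.5, perBranch = TRUE,
                             minCellsPerWindow = 25)
  scopes <- vapply(w, `[[`, character(1), "scope")
  expect_true("pre-branch" %in% scopes)
  expect_gte(length(unique(scopes)), 3L)
  br <- branchIds(bb$ordering)
  for (win in w[scopes != "pre-branch"])
    expect_equal(length(unique(br[win$cells])), 1L)
})

test_that("the tree-ensemble importance finds a planted regulator", {
  hits <- 0
  for (seed in 1:20) {
    wir <- data.frame(regulator = "reg01", target = "tgt01",
                      coefficient = 2)
    s <- simulateRegulatoryPanel(120, wir, noiseSd = 0.1, nDecoys = 8,
                                 seed = seed)
    win <- list(center = 0.5, lo = 0, hi = 1, cells = 1:120,
                scope = "all")
    grn <- inferGRNWindow(win, s$cs, geneIds(s$cs), nTrees = 200,
                          seed = seed)
    expect_equal(dim(grn), c(10L, 10L))
    expect_true(all(diag(grn) == 0))
    expect_true(all(grn >= 0))
    if (rownames(grn)[which.max(grn[, "tgt01"])] == "reg01")
      hits <- hits + 1
  }
  expect_gte(hits, 18L)
})

test_that("tree-ensemble importance is reproducible and respects seeds", {
  wir <- data.frame(regulator = "reg01", target = "tgt01",
                    coefficient = 2)
  s <- simulateRegulatoryPanel(100, wir, noiseSd = 0.1, nDecoys = 5,
                               seed = 1)
  win <- list(center = 0.5, lo = 0, hi = 1, cells = 1:100,
              scope = "all")
  g1 <- inferGRNWindow(win, s$cs, geneIds(s$cs), nTrees = 100, seed = 7)
  g2 <- inferGRNWindow(win, s$cs, geneIds(s$cs), nTrees = 100, seed = 7)
  expect_identical(g1, g2)
  g3 <- inferGRNWindow(win, s$cs, geneIds(s$cs), nTrees = 100, seed = 8)
  expect_false(identical(g1, g3))
  expect_error(inferGRNWindow(win, s$cs, geneIds(s$cs)), "seed")
})

test_that("constant genes are neutralized with a warning", {
  set.seed(51)
  v <- cbind(a = rnorm(50) + 5, b = rnorm(50) + 5, c = rep(2, 50))
  cs <- makeCS(abs(v))
  win <- list(center = 0.5, lo = 0, hi = 1, cells = 1:50, scope = "all")
  expect_warning(grn <- inferGRNWindow(win, cs, c("a", "b", "c"),
                                       nTrees = 50, seed = 1),
                 "constant")
  expect_true(all(grn["c", ] == 0))
  expect_true(all(grn[, "c"] == 0))
})

test_that("neighborhood extraction recovers a planted module", {
  set.seed(52)
  n <- 200
  core <- rnorm(n)
  # three genes tightly coupled to the core, six independent decoys
  v <- cbind(core = core,
             p1 = core + rnorm(n, sd = 0.2),
             p2 = core + rnorm(n, sd = 0.2),
             p3 = -core + rnorm(n, sd = 0.2),
             matrix(rnorm(n * 6), n, 6,
                    dimnames = list(NULL, paste0("d", 1:6))))
  cs <- makeCS(v - min(v))
  win <- list(center = 0.5, lo = 0, hi = 1, cells = 1:n, scope = "all")
  grn <- inferGRNWindow(win, cs, colnames(v), nTrees = 200, seed = 3)
  nb <- extractNeighborhood(grn, cs, win, "core", kPartners = 3)
  expect_setequal(nb$partners, c("p1", "p2", "p3"))
  expect_true(all(nb$edges$abs_cor >= 0 & nb$edges$abs_cor <= 1))

  # a core uncorrelated with everything admits nobody
  set.seed(53)
  v2 <- matrix(rnorm(n * 5), n, 5,
               dimnames = list(NULL, c("core", paste0("d", 1:4))))
  cs2 <- makeCS(v2 - min(v2))
  grn2 <- inferGRNWindow(win, cs2, colnames(v2), nTrees = 100, seed = 4)
  nb2 <- extractNeighborhood(grn2, cs2, win, "core", kPartners = 3,
                             mutualThreshold = 0.3)
  expect_length(nb2$partners, 0L)

  # constant core errors
  v3 <- cbind(core = rep(1, n), d1 = rnorm(n) + 5)
  cs3 <- makeCS(abs(v3))
  grn3 <- matrix(0, 2, 2, dimnames = list(colnames(v3), colnames(v3)))
  expect_error(extractNeighborhood(grn3, cs3, win, "core"), "constant")
})

test_that("tie-broken candidate order is deterministic by gene id", {
  # identical importances: admission order falls back to correlation
  # then gene id
  n <- 100
  set.seed(54)
  core <- rnorm(n)
  v <- cbind(core = core, bGene = core + rnorm(n, sd = 1e-6),
             aGene = core + rnorm(n, sd = 1e-6))
  cs <- makeCS(v - min(v))
  grn <- matrix(0, 3, 3, dimnames = list(colnames(v), colnames(v)))
  win <- list(center = 0.5, lo = 0, hi = 1, cells = 1:n, scope = "all")
  nb <- extractNeighborhood(grn, cs, win, "core", kPartners = 1,
                            mutualThreshold = 0.3)
  # zero importance everywhere: rank by |cor| (near 1 for both), then id
  expect_length(nb$partners, 1L)
})

test_that("correlation degrees match definitions and a brute-force loop", {
  # two perfectly correlated genes across three cells
  v <- cbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), g3 = c(5, 1, 4))
  cs <- makeCS(v)
  win <- list(center = 0.5, lo = 0, hi = 1, cells = 1:3, scope = "all")
  d <- correlationDegrees(win, cs, c("g1", "g2"))
  expect_equal(d$geneCorr, 1, tolerance = 1e-12)

  # block panel: brute-force mean absolute pairwise correlation
  set.seed(55)
  v2 <- matrix(rnorm(60 * 8), 60, 8)
  v2[, 5:8] <- v2[, 1:4] + matrix(rnorm(60 * 4, sd = 0.5), 60, 4)
  colnames(v2) <- paste0("g", 1:8)
  cs2 <- makeCS(v2 - min(v2))
  win2 <- list(center = 0.5, lo = 0, hi = 1, cells = 1:60, scope = "all")
  d2 <- correlationDegrees(win2, cs2, colnames(v2))
  acc <- 0; np <- 0
  for (i in 1:7) for (j in (i + 1):8) {
    acc <- acc + abs(cor(v2[, i], v2[, j])); np <- np + 1
  }
  expect_equal(d2$geneCorr, acc / np, tolerance = 1e-12)
  ccAcc <- 0; ncp <- 0
  for (i in 1:59) for (j in (i + 1):60) {
    ccAcc <- ccAcc + cor(v2[i, ], v2[j, ]); ncp <- ncp + 1
  }
  expect_equal(d2$cellCorr, ccAcc / ncp, tolerance = 1e-12)

  # gene_corr is invariant to positive affine rescaling of genes
  v3 <- sweep(sweep(v2, 2, runif(8, 0.5, 3), "*"), 2, runif(8), "+")
  colnames(v3) <- colnames(v2)
  d3 <- correlationDegrees(win2, makeCS(v3 - min(v3)), colnames(v3))
  expect_equal(d3$geneCorr, d2$geneCorr, tolerance = 1e-12)

  # null panel: gene_corr close to the E|r| ~ 0.8/sqrt(n) null level
  set.seed(56)
  nC <- 500
  vN <- matrix(rnorm(nC * 12), nC, 12,
               dimnames = list(NULL, paste0("g", 1:12)))
  winN <- list(center = 0.5, lo = 0, hi = 1, cells = 1:nC,
               scope = "all")
  dN <- correlationDegrees(winN, makeCS(vN - min(vN)),
                           paste0("g", 1:12))
  expect_lt(abs(dN$geneCorr - 0.8 / sqrt(nC)), 3 * 0.03)
  # ratio undefined when the cell correlation is at the noise floor
  expect_true(is.na(dN$ratio))
})
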