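test_that("the Gamma MLE honors its contracts on edge cases", {
  expect_error(fitGammaMLE(c(1, 0, 2)), "strictly positive")
  # too few observations: not estimable
  f <- fitGammaMLE(rep(2, 5), minObs = 20)
  expect_false(f$converged)
  expect_true(is.na(f$a))
  # zero variance: degenerate (shape -> infinity limit)
  f2 <- fitGammaMLE(rep(3, 50))
  expect_true(f2$degenerate)
  expect_false(f2$converged)
})

test_that("the Gamma MLE satisfies the first-moment identity exactly", {
  set.seed(61)
  for (rep in 1:20) {
    x <- rgamma(200, shape = runif(1, 0.3, 8),
                scale = runif(1, 0.5, 100))
    f <- fitGammaMLE(x)
    expect_true(f$converged)
    expect_equal(f$a * f$b, mean(x), tolerance = 1e-9)
    expect_gt(f$a, 0); expect_gt(f$b, 0)
    # invariant to observation order
    f2 <- fitGammaMLE(rev(x))
    expect_equal(f2$a, f$a)
  }
})

test_that("the Gamma MLE recovers known parameters within Fisher bounds", {
  set.seed(62)
  inside <- 0
  for (rep in 1:100) {
    x <- rgamma(1000, shape = 2, scale = 5)
    f <- fitGammaMLE(x)
    if (f$a >= 1.8 && f$a <= 2.2 && f$b >= 4.5 && f$b <= 5.5)
      inside <- inside + 1
  }
  expect_gte(inside, 95L)
})

test_that("MLE at least matches method-of-moments accuracy for the shape", {
  set.seed(63)
  errML <- errMM <- numeric(200)
  for (rep in 1:200) {
    x <- rgamma(200, shape = 1.5, scale = 10)
    errML[rep] <- fitGammaMLE(x)$a - 1.5
    errMM[rep] <- mean(x)^2 / var(x) - 1.5
  }
  expect_lte(sqrt(mean(errML^2)), sqrt(mean(errMM^2)))
})

test_that("quadrant classification applies the fixed thresholds", {
  c1 <- classifyBurstQuadrant(1.0, 50)
  expect_equal(c1$quadrant, "high-freq small-burst")
  expect_false(c1$bursty)
  c2 <- classifyBurstQuadrant(0.1, 500)
  expect_equal(c2$quadrant, "low-freq large-burst")
  expect_true(c2$bursty)
  c3 <- classifyBurstQuadrant(1.0, 500)
  expect_equal(c3$quadrant, "high-freq large-burst")
  expect_true(c3$bursty)
  c4 <- classifyBurstQuadrant(0.1, 50)
  expect_equal(c4$quadrant, "low-freq small-burst")
  expect_true(c4$bursty)
  expect_true(is.na(classifyBurstQuadrant(NA, NA)$quadrant))

  # dataset-mean mode uses the supplied fit population as thresholds
  cm <- classifyBurstQuadrant(1, 10, mode = "dataset-mean",
                              allA = c(0.5, 1.0), allB = c(5, 25))
  expect_equal(cm$quadrant, "high-freq small-burst")
})

test_that("bursty fraction matches a manual count on synthetic genes", {
  set.seed(64)
  nG <- 100
  aTrue <- exp(runif(nG, log(0.05), log(5)))
  bTrue <- exp(runif(nG, log(5), log(2000)))
  # keep parameters away from the thresholds so classification of the
  # estimates matches the truth
  aTrue[abs(log(aTrue / 0.33)) < 0.5] <- 1.5
  bTrue[abs(log(bTrue / 200)) < 0.5] <- 20
  gp <- lapply(seq_len(nG), function(i) list(a = aTrue[i], b = bTrue[i]))
  sim <- simulateBurstyExpression(1500, gp, tau = runif(1500),
                                  dropoutRate = 0, seed = 64)
  ord <- manualOrdering(cellIds(sim$cs), runif(1500))
  win <- list(list(center = 0.5, lo = 0, hi = 1, cells = 1:1500,
                   scope = "all"))
  bt <- burstTrajectories(sim$cs, ord, win)
  manual <- mean(!(aTrue > 0.33 & bTrue < 200))
  expect_equal(bt$summary$bursty_fraction, manual, tolerance = 1e-12)
  # mean expression includes zeros and is the plain window average
  expect_equal(bt$summary$mean_expression, mean(exprValues(sim$cs)),
               tolerance = 1e-12)
})

test_that("windowed trajectories recover parameter trends in pseudotime", {
  set.seed(65)
  n <- 600
  tau <- runif(n)
  gp <- lapply(1:40, function(i)
    list(a = function(t) 0.5 + 2 * t,
         b = function(t) 80 * exp(-2 * t) + 20))
  sim <- simulateBurstyExpression(n, gp, tau, dropoutRate = 0.3,
                                  seed = 65)
  ord <- manualOrdering(cellIds(sim$cs), tau)
  w <- makePseudotimeWindows(ord, nWindows = 8, overlapFraction = 0.25)
  bt <- burstTrajectories(sim$cs, ord, w)
  s <- bt$summary
  expect_gte(cor(s$center, s$mean_a, method = "spearman"), 0.8)
  expect_lte(cor(s$center, s$mean_b, method = "spearman"), -0.8)

  # stationary generator: no monotone trend across seeds
  rhoNull <- vapply(1:5, function(seed) {
    gp0 <- lapply(1:40, function(i) list(a = 2, b = 30))
    sim0 <- simulateBurstyExpression(n, gp0, tau, dropoutRate = 0.3,
                                     seed = seed)
    bt0 <- burstTrajectories(sim0$cs, ord, w)
    cor(bt0$summary$center, bt0$summary$mean_a, method = "spearman")
  }, numeric(1))
  expect_lte(median(abs(rhoNull)), 0.3)
})
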