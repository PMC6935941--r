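# Shared fixtures and independent oracles. Oracles are deliberately
# written as plain double loops / dense solves, independent of the
# package's computation paths.

# Quick cells x genes CellStateSet from a bare matrix.
makeCS <- function(values, reduced = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("c%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("g%03d", seq_len(ncol(values)))
  CellStateSet(values, reduced = reduced)
}

# Brute-force local density: explicit per-cell loop over all others.
bruteRho <- function(coords, sigma) {
  m <- nrow(coords)
  rho <- numeric(m)
  for (i in seq_len(m)) {
    s <- 0
    for (j in seq_len(m)) {
      d2 <- sum((coords[i, ] - coords[j, ])^2)
      s <- s + exp(-d2 / (2 * sigma^2))
    }
    rho[i] <- s
  }
  rho
}

# Brute-force decision-graph delta with the package's tie rule
# (lower cell index counts as lower pseudo-potential).
bruteDelta <- function(coords, eTilde, idx = seq_len(nrow(coords))) {
  k <- nrow(coords)
  delta <- numeric(k)
  for (i in seq_len(k)) {
    lower <- which(eTilde < eTilde[i] |
                     (eTilde == eTilde[i] & idx < idx[i]))
    if (!length(lower)) {
      delta[i] <- max(vapply(setdiff(seq_len(k), i), function(j)
        sqrt(sum((coords[i, ] - coords[j, ])^2)), numeric(1)))
    } else {
      delta[i] <- min(vapply(lower, function(j)
        sqrt(sum((coords[i, ] - coords[j, ])^2)), numeric(1)))
    }
  }
  delta
}

# Dense direct solve of the teleported stationary equation.
denseStationary <- function(graph, epsilon) {
  m <- graph@nCells
  P <- matrix(0, m, m)
  P[cbind(graph@from, graph@to)] <- graph@conditional
  v <- rep(0, m)
  agg <- rowsum(graph@weight, graph@from)
  v[as.integer(rownames(agg))] <- agg
  v <- v / sum(graph@weight)
  solve(diag(m) - (1 - epsilon) * t(P), epsilon * v)
}

# Standard backbone run on a simulated trajectory: PCA-reduced distance
# space (10 components), default parameters.
runBackbone <- function(sim, rootHintN = 10) {
  cs <- preprocessCells(sim$cs, logTransform = FALSE, reduceTo = 10)
  ctx <- deriveSigma(cs)
  field <- computePseudoPotential(cs, ctx)
  tree <- growBackboneTree(cs, field)
  hint <- sim$truth$cells$cell_id[order(sim$truth$cells$t)[
    seq_len(rootHintN)]]
  ordering <- projectCells(tree, cs, rootHint = hint)
  list(cs = cs, ctx = ctx, field = field, tree = tree,
       ordering = ordering)
}

# Random-walk solution for an ordering.
solveWalk <- function(ordering, cs, chi = 30, k = 10, epsilon = 0.01) {
  g <- buildWeightGraph(ordering, cs, chi = chi, kNeighbors = k)
  g <- conditionalProbabilities(g)
  stationaryDistribution(g, epsilon = epsilon)
}

# The critical-transition regulatory panel: coupling weakens mildly and
# per-gene noise grows toward the designed transition at tau = 0.5.
transitionPanel <- function(nCells = 800, seed = 1) {
  wiring <- data.frame(
    regulator = rep(sprintf("reg%02d", 1:5), each = 2),
    target = sprintf("tgt%02d", 1:10), coefficient = 1)
  coup <- function(t) 1 - 0.3 * exp(-(t - 0.5)^2 / (2 * 0.15^2))
  nz <- function(t) 0.5 + 2.5 * exp(-(t - 0.5)^2 / (2 * 0.15^2))
  simulateRegulatoryPanel(nCells, wiring, couplingProfile = coup,
                          noiseSd = nz, nDecoys = 5, seed = seed)
}

nodeDeg <- function(tree) tabulate(treeEdges(tree),
                                   length(tree@nodeCells))
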