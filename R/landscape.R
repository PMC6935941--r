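#' Build the pseudotime-weighted directed cell graph
#'
#' The directed edge from cell alpha to cell beta carries weight
#' W0 * exp(-chi * (tau_alpha - tau_beta)): moves forward in pseudotime
#' are exponentially favored, with sensitivity chi (default 30). The edge
#' support is restricted to the symmetrized k-nearest-neighbor graph in
#' state space (both directions are present, weights are asymmetric);
#' without that restriction the weight rule would connect arbitrarily
#' distant cells. `kNeighbors = NULL` requests the dense all-pairs graph.
#'
#' @param ordering a [CellOrdering-class] (provides tau).
#' @param cs the [CellStateSet-class].
#' @param chi pseudotime sensitivity (default 30).
#' @param kNeighbors neighborhood size (default 10); must be < nCells.
#'   `NULL` for the dense graph.
#' @param W0 base weight (default 1; the downstream probabilities are
#'   independent of it).
#' @return a [TransitionGraph-class] with weights only.
#' @export
buildWeightGraph <- function(ordering, cs, chi = 30, kNeighbors = 10L,
                             W0 = 1) {
  .checkScalar(chi, "chi", 0, Inf, openLo = TRUE)
  .checkScalar(W0, "W0", 0, Inf, openLo = TRUE)
  m <- nCells(cs)
  tau <- ordering@pseudotime
  if (length(tau) != m) stop("ordering does not match the cell set")
  if (is.null(kNeighbors)) {
    from <- rep(seq_len(m), each = m)
    to <- rep(seq_len(m), times = m)
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    kNeighbors <- m - 1L
  } else {
    kNeighbors <- as.integer(kNeighbors)
    if (kNeighbors >= m)
      stop("kNeighbors (", kNeighbors, ") must be smaller than the ",
           "number of cells (", m, ")")
    if (kNeighbors < 1L) stop("kNeighbors must be >= 1")
    d <- as.matrix(dist(stateCoords(cs)))
    diag(d) <- Inf
    nn <- t(apply(d, 1L, function(r) order(r)[seq_len(kNeighbors)]))
    from <- rep(seq_len(m), each = kNeighbors)
    to <- as.integer(t(nn))
    # symmetrize the support: add the reverse of every edge, dedupe
    key <- paste(c(from, to), c(to, from))
    keep <- !duplicated(key)
    both <- cbind(c(from, to), c(to, from))[keep, , drop = FALSE]
    from <- both[, 1L]; to <- both[, 2L]
  }
  w <- W0 * exp(-chi * (tau[from] - tau[to]))
  new("TransitionGraph", from = as.integer(from), to = as.integer(to),
      weight = as.numeric(w), nCells = as.integer(m), W0 = W0, chi = chi,
      kNeighbors = as.integer(kNeighbors))
}

#' Fill in conditional move probabilities
#'
#' The probability that the walker standing at cell beta moves to cell
#' alpha is the relative out-link weight
#' p(beta -> alpha) = W(beta -> alpha) / sum of W over beta's out-edges.
#' Each cell's out-probabilities sum to 1, and the result is independent
#' of W0.
#'
#' @param graph a [TransitionGraph-class] with weights.
#' @return the graph with the `conditional` slot filled.
#' @export
conditionalProbabilities <- function(graph) {
  totals <- rowsum(graph@weight, graph@from)
  tot <- numeric(graph@nCells)
  tot[as.integer(rownames(totals))] <- totals[, 1L]
  if (any(tot[unique(graph@from)] <= 0))
    stop("cell with zero total out-weight")
  graph@conditional <- graph@weight / tot[graph@from]
  validObject(graph)
  graph
}

#' Solve the teleported stationary visit distribution
#'
#' Power iteration on p = (1 - eps) * P^T p + eps * v, where P holds the
#' conditional move probabilities and the teleportation vector v gives
#' each cell its total out-link weight divided by the total weight of all
#' edges (`teleport = "out-weight"`, the default; `"in-weight"` uses the
#' total weight of links *into* the cell instead). Teleportation makes
#' the solution unique and strictly positive.
#'
#' @param graph a [TransitionGraph-class] with conditionals.
#' @param epsilon teleportation rate in (0, 1), default 0.01.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param maxIter iteration cap (default 1e4).
#' @param teleport `"out-weight"` or `"in-weight"`.
#' @return the graph with the `stationary` slot filled.
#' @export
stationaryDistribution <- function(graph, epsilon = 0.01, tol = 1e-10,
                                   maxIter = 10000L,
                                   teleport = c("out-weight",
                                                "in-weight")) {
  teleport <- match.arg(teleport)
  .checkScalar(epsilon, "epsilon", 0, 1, openLo = TRUE, openHi = TRUE)
  if (!length(graph@conditional))
    stop("call conditionalProbabilities() first")
  m <- graph@nCells
  totalW <- sum(graph@weight)
  v <- numeric(m)
  sums <- rowsum(graph@weight,
                 if (teleport == "out-weight") graph@from else graph@to)
  v[as.integer(rownames(sums))] <- sums[, 1L]
  v <- v / totalW
  P <- Matrix::sparseMatrix(i = graph@from, j = graph@to,
                            x = graph@conditional, dims = c(m, m))
  p <- rep(1 / m, m)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    pNew <- as.numeric((1 - epsilon) * Matrix::crossprod(P, p)) +
      epsilon * v
    res <- sum(abs(pNew - p))
    p <- pNew
    if (res <= tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("power iteration did not converge in ", maxIter,
         " iterations (L1 residual ", format(res, digits = 3), ")")
  graph@stationary <- p / sum(p)
  graph@epsilon <- epsilon
  graph@teleport <- teleport
  validObject(graph)
  graph
}

#' Per-cell landscape potential
#'
#' E_alpha = -log p_alpha: cells the pseudotime-weighted walker visits
#' often sit low in the landscape. Unlike the pseudo-potential (a pure
#' density measure), this potential inherits the direction of
#' development through the pseudotime-dependent weights.
#'
#' @param graph a [TransitionGraph-class] with a converged stationary
#'   distribution.
#' @return named numeric vector of potentials (natural-log units).
#' @export
cellPotentials <- function(graph) {
  p <- stationaryProbs(graph)
  if (any(p <= 0))
    stop("non-positive stationary probability: teleportation should ",
         "have prevented this")
  -log(p)
}

#' Render the landscape surface on a 2-D grid
#'
#' Cells are embedded in 2-D (deterministic PCA of the expression values
#' by default, or a user-supplied embedding), each grid point takes the
#' potential of its nearest embedded cell, and the grid is smoothed by a
#' separable Gaussian kernel measured in grid cells. The backbone tree is
#' pushed through the same embedding as an overlay.
#'
#' @param potentials named per-cell potentials from [cellPotentials()].
#' @param cs the [CellStateSet-class].
#' @param tree optional [BackboneTree-class] for the overlay.
#' @param method `"pca"` (deterministic) or `"custom"` (requires
#'   `embedding`).
#' @param embedding optional cells x 2 coordinate matrix.
#' @param gridResolution grid points per axis (default 200, >= 16).
#' @param smoothingBandwidth Gaussian sd in grid cells (default 2; 0
#'   disables smoothing).
#' @return a [LandscapeSurface-class].
#' @export
buildLandscapeSurface <- function(potentials, cs, tree = NULL,
                                  method = c("pca", "custom"),
                                  embedding = NULL,
                                  gridResolution = 200L,
                                  smoothingBandwidth = 2) {
  method <- match.arg(method)
  gridResolution <- as.integer(gridResolution)
  .checkScalar(gridResolution, "gridResolution", 16, Inf)
  .checkScalar(smoothingBandwidth, "smoothingBandwidth", 0, Inf)
  m <- nCells(cs)
  if (length(potentials) != m)
    stop("need one potential per cell")
  nodeEmb <- NULL
  if (method == "pca") {
    v <- exprValues(cs)
    pc <- prcomp(v, center = TRUE, scale. = FALSE, rank. = 2L)
    if (ncol(pc$x) < 2L || any(pc$sdev[1:2] == 0))
      stop("degenerate embedding: expression matrix has fewer than two ",
           "directions of variance")
    rot <- pc$rotation
    # deterministic sign: largest-magnitude loading positive
    for (j in 1:2) if (rot[which.max(abs(rot[, j])), j] < 0)
      rot[, j] <- -rot[, j]
    emb <- sweep(v, 2L, pc$center) %*% rot[, 1:2]
    if (!is.null(tree)) {
      nodeExpr <- v[tree@nodeCells, , drop = FALSE]
      nodeEmb <- sweep(nodeExpr, 2L, pc$center) %*% rot[, 1:2]
    }
  } else {
    if (is.null(embedding) || ncol(embedding) != 2L ||
        nrow(embedding) != m)
      stop("method = 'custom' requires a cells x 2 'embedding'")
    emb <- as.matrix(embedding)
    if (any(apply(emb, 2L, sd) == 0))
      stop("degenerate embedding: zero variance axis")
    if (!is.null(tree)) {
      # custom embeddings carry no map for new points: snap nodes to
      # their source cells' embedded positions
      nodeEmb <- emb[tree@nodeCells, , drop = FALSE]
    }
  }
  gx <- seq(min(emb[, 1L]), max(emb[, 1L]), length.out = gridResolution)
  gy <- seq(min(emb[, 2L]), max(emb[, 2L]), length.out = gridResolution)
  # nearest embedded cell per grid point, chunked to bound memory
  nnVal <- matrix(NA_real_, gridResolution, gridResolution)
  chunk <- max(1L, floor(2e6 / m))
  gridPts <- cbind(rep(gx, times = gridResolution),
                   rep(gy, each = gridResolution))
  for (s in seq(1L, nrow(gridPts), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(gridPts))
    d2 <- outer(gridPts[idx, 1L], emb[, 1L], "-")^2 +
      outer(gridPts[idx, 2L], emb[, 2L], "-")^2
    nnVal[idx] <- potentials[max.col(-d2, ties.method = "first")]
  }
  # nnVal is indexed [x, y] via the gridPts layout; store as y-rows
  nnVal <- t(nnVal)
  sm <- .gaussianSmooth2d(nnVal, smoothingBandwidth)
  new("LandscapeSurface", embedding = unname(as.matrix(emb)),
      gridX = gx, gridY = gy, values = sm, nnValues = nnVal,
      smoothingBandwidth = smoothingBandwidth,
      backboneNodes = if (is.null(nodeEmb)) matrix(numeric(0), 0, 2)
                      else unname(as.matrix(nodeEmb)),
      backboneEdges = if (is.null(tree)) matrix(integer(0), 0, 2)
                      else tree@edges)
}

# Separable Gaussian smoothing with kernel renormalization at the
# borders; bandwidth in grid cells, 0 = identity.
.gaussianSmooth2d <- function(mat, bandwidth) {
  if (bandwidth <= 0) return(mat)
  half <- max(1L, ceiling(4 * bandwidth))
  kern <- exp(-((-half:half)^2) / (2 * bandwidth^2))
  smooth1 <- function(x) {
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      kk <- kern[(lo - i + half + 1L):(hi - i + half + 1L)]
      out[i] <- sum(x[lo:hi] * kk) / sum(kk)
    }
    out
  }
  tmp <- apply(mat, 2L, smooth1)
  t(apply(tmp, 1L, smooth1))
}
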