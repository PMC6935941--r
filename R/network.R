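#' Tile pseudotime with overlapping windows
#'
#' Windows of equal width tile `[0, 1]` so that consecutive windows share
#' `overlapFraction` of their width. With `perBranch = TRUE` the tiling is
#' intersected with branch scopes: cells on the chains between the root
#' and the first branch point form the joint `"pre-branch"` scope, and
#' every other chain is windowed separately, so no window mixes cells
#' from two post-branch branches. Windows with fewer than
#' `minCellsPerWindow` members are merged with their right neighbor (the
#' last window merges leftward); if everything collapses, one window
#' holds all of the scope's cells.
#'
#' @param ordering a [CellOrdering-class].
#' @param nWindows number of windows tiling `[0, 1]` (>= 2).
#' @param overlapFraction fraction of a window shared with its successor
#'   (in `[0, 1)`, default 0.5).
#' @param perBranch build windows per branch scope (default FALSE).
#' @param minCellsPerWindow minimum occupancy (default 30).
#' @return list of windows, each a list with elements `center`, `lo`,
#'   `hi`, `cells` (integer indices), `scope`.
#' @export
makePseudotimeWindows <- function(ordering, nWindows = 10L,
                                  overlapFraction = 0.5,
                                  perBranch = FALSE,
                                  minCellsPerWindow = 30L) {
  nWindows <- as.integer(nWindows)
  .checkScalar(nWindows, "nWindows", 2, Inf)
  .checkScalar(overlapFraction, "overlapFraction", 0, 1, openHi = TRUE)
  tau <- ordering@pseudotime
  if (length(tau) < minCellsPerWindow)
    stop("too few cells (", length(tau), ") for windows of at least ",
         minCellsPerWindow, " cells")
  w <- 1 / (1 + (nWindows - 1) * (1 - overlapFraction))
  starts <- (seq_len(nWindows) - 1L) * (1 - overlapFraction) * w
  bounds <- cbind(lo = starts, hi = pmin(1, starts + w))

  scopes <- if (perBranch) .branchScopes(ordering) else
    list(all = seq_along(tau))
  out <- list()
  for (sc in names(scopes)) {
    cells <- scopes[[sc]]
    wins <- lapply(seq_len(nWindows), function(i) {
      sel <- cells[tau[cells] >= bounds[i, 1L] &
                     tau[cells] <= bounds[i, 2L]]
      list(center = mean(bounds[i, ]), lo = bounds[i, 1L],
           hi = bounds[i, 2L], cells = sel, scope = sc)
    })
    wins <- Filter(function(x) length(x$cells) > 0L, wins)
    # collapse adjacent windows holding the identical cell set (all the
    # mass may sit in the overlap region)
    i <- 1L
    while (i < length(wins)) {
      if (identical(wins[[i]]$cells, wins[[i + 1L]]$cells)) {
        wins[[i]]$lo <- min(wins[[i]]$lo, wins[[i + 1L]]$lo)
        wins[[i]]$hi <- max(wins[[i]]$hi, wins[[i + 1L]]$hi)
        wins[[i]]$center <- mean(c(wins[[i]]$lo, wins[[i]]$hi))
        wins[[i + 1L]] <- NULL
      } else i <- i + 1L
    }
    # merge undersized windows into the next (or previous at the end)
    i <- 1L
    while (i <= length(wins)) {
      if (length(wins[[i]]$cells) >= minCellsPerWindow ||
          length(wins) == 1L) { i <- i + 1L; next }
      j <- if (i < length(wins)) i + 1L else i - 1L
      merged <- list(
        center = NA_real_,
        lo = min(wins[[i]]$lo, wins[[j]]$lo),
        hi = max(wins[[i]]$hi, wins[[j]]$hi),
        cells = sort(unique(c(wins[[i]]$cells, wins[[j]]$cells))),
        scope = sc)
      merged$center <- mean(c(merged$lo, merged$hi))
      wins[[min(i, j)]] <- merged
      wins[[max(i, j)]] <- NULL
      i <- 1L  # restart the scan after a merge
    }
    out <- c(out, wins)
  }
  out
}

# Branch scopes: chains on the path root -> first branch point form the
# joint "pre-branch" scope; every other chain is its own scope.
.branchScopes <- function(ordering) {
  tree <- ordering@tree
  deg <- nodeDegrees(tree)
  nChains <- max(ordering@chainOfEdge, 1L)
  if (nrow(tree@edges) == 0L) {
    # external ordering without tree geometry: scope by branch label
    ids <- sort(unique(ordering@branchId))
    if (length(ids) <= 1L)
      return(list(`pre-branch` = seq_along(ordering@pseudotime)))
    scopes <- lapply(ids, function(b) which(ordering@branchId == b))
    names(scopes) <- paste0("branch", ids)
    return(scopes)
  }
  if (all(deg < 3L))
    return(list(`pre-branch` = seq_along(ordering@pseudotime)))
  # walk from the root until the first branch point, collecting chains
  root <- ordering@rootNode
  adj <- treeAdjacency(tree)
  preChains <- integer(0)
  v <- root
  prevEdge <- 0L
  while (deg[v] < 3L) {
    nextEdges <- setdiff(adj[[v]], prevEdge)
    if (!length(nextEdges)) break
    k <- nextEdges[1L]
    preChains <- c(preChains, ordering@chainOfEdge[k])
    v <- setdiff(tree@edges[k, ], v)
    prevEdge <- k
  }
  preChains <- unique(preChains)
  scopes <- list()
  pre <- which(ordering@branchId %in% preChains)
  if (length(pre)) scopes[["pre-branch"]] <- pre
  for (ch in setdiff(seq_len(nChains), preChains)) {
    cells <- which(ordering@branchId == ch)
    if (length(cells)) scopes[[paste0("branch", ch)]] <- cells
  }
  scopes
}

#' Infer a regulator-to-target importance matrix for one window
#'
#' For each target gene in the panel, the window's expression of all
#' other panel genes is used to grow a randomized regression-tree
#' ensemble (square-root feature subsampling, uniform random cut points);
#' a regulator's importance for the target is its total variance
#' reduction, averaged over trees. Genes that are all-zero in the window
#' are removed first; constant genes get zero importance with a warning.
#' Deterministic given `seed`.
#'
#' @param window one window from [makePseudotimeWindows()].
#' @param cs the [CellStateSet-class].
#' @param panel character gene ids to analyze.
#' @param nTrees ensemble size (default 500).
#' @param seed integer seed (mandatory).
#' @param minNode minimum node size to attempt a split (default 5).
#' @return panel x panel importance matrix (regulators in rows, targets
#'   in columns, diagonal 0).
#' @export
inferGRNWindow <- function(window, cs, panel, nTrees = 500L, seed,
                           minNode = 5L) {
  if (missing(seed)) stop("'seed' is mandatory for reproducibility")
  panel <- as.character(panel)
  miss <- setdiff(panel, geneIds(cs))
  if (length(miss)) stop("panel genes not found: ",
                         paste(miss, collapse = ", "))
  x <- exprValues(cs)[window$cells, panel, drop = FALSE]
  allZero <- colSums(x != 0) == 0L
  if (any(allZero)) x <- x[, !allZero, drop = FALSE]
  active <- colnames(x)
  imp <- matrix(0, length(panel), length(panel),
                dimnames = list(panel, panel))
  if (length(active) < 2L) return(imp)
  sds <- apply(x, 2L, sd)
  constant <- sds == 0
  if (any(constant))
    warning("constant gene(s) in window: ",
            paste(active[constant], collapse = ", "),
            " (importances set to 0)")
  usable <- active[!constant]
  if (length(usable) < 2L) return(imp)
  mtry <- max(1L, as.integer(ceiling(sqrt(length(usable) - 1L))))
  for (ti in seq_along(usable)) {
    target <- usable[ti]
    regs <- setdiff(usable, target)
    yv <- x[, target] / sds[match(target, active)]
    scores <- .etImportanceCpp(x[, regs, drop = FALSE], yv,
                               as.integer(nTrees), mtry,
                               as.integer(minNode),
                               as.integer(seed) + ti)
    imp[regs, target] <- scores
  }
  imp
}

#' Extract the neighborhood network of a core gene
#'
#' Candidates are ranked by their symmetrized importance with the core
#' gene (the larger of the two directed scores), ties broken by absolute
#' Pearson correlation with the core and then by gene id. Candidates are
#' admitted greedily while their mean absolute correlation with the
#' already-admitted members (including the core) stays at or above
#' `mutualThreshold`, until `kPartners` genes are admitted: the result is
#' a module of genes closely tied to the core and to each other.
#'
#' @param grn importance matrix from [inferGRNWindow()].
#' @param cs the [CellStateSet-class].
#' @param window the window the GRN was inferred on.
#' @param coreGene gene id of the core node.
#' @param kPartners maximum number of partners (default 6).
#' @param mutualThreshold admission threshold on the mean absolute
#'   correlation (default 0.3).
#' @return list with `core`, `partners` (character), and `edges`
#'   (data.frame of pairwise absolute correlations among core+partners).
#' @export
extractNeighborhood <- function(grn, cs, window, coreGene,
                                kPartners = 6L, mutualThreshold = 0.3) {
  panel <- rownames(grn)
  if (!coreGene %in% panel) stop("core gene not in the panel")
  x <- exprValues(cs)[window$cells, panel, drop = FALSE]
  if (sd(x[, coreGene]) == 0)
    stop("core gene '", coreGene, "' is constant in this window")
  others <- setdiff(panel, coreGene)
  score <- pmax(grn[coreGene, others], grn[others, coreGene])
  coreCor <- vapply(others, function(g) {
    if (sd(x[, g]) == 0) 0 else abs(cor(x[, coreGene], x[, g]))
  }, numeric(1L))
  ord <- others[order(-score, -coreCor, others)]
  admitted <- character(0)
  for (g in ord) {
    if (length(admitted) >= kPartners) break
    if (sd(x[, g]) == 0) next
    withCors <- vapply(c(coreGene, admitted), function(h)
      abs(cor(x[, g], x[, h])), numeric(1L))
    if (mean(withCors) >= mutualThreshold)
      admitted <- c(admitted, g)
  }
  memb <- c(coreGene, admitted)
  edges <- NULL
  if (length(memb) > 1L) {
    cc <- abs(cor(x[, memb, drop = FALSE]))
    pairs <- which(upper.tri(cc), arr.ind = TRUE)
    edges <- data.frame(gene1 = memb[pairs[, 1L]],
                        gene2 = memb[pairs[, 2L]],
                        abs_cor = cc[pairs])
  }
  list(core = coreGene, partners = admitted, edges = edges)
}

#' Gene-gene and cell-cell correlation degrees in one window
#'
#' The gene correlation degree is the mean absolute Pearson correlation
#' over unordered pairs of non-constant panel genes (computed across the
#' window's cells); the cell correlation degree is the mean (signed)
#' Pearson correlation over unordered pairs of cells (computed across the
#' panel genes). Their ratio is the critical-transition index: it rises
#' toward a maximum as cells pass through a fate transition, where
#' cell-cell correlation collapses faster than gene-gene correlation.
#' The ratio is only reported when the cell correlation degree exceeds
#' `ratioFloor`.
#'
#' @param window one window from [makePseudotimeWindows()].
#' @param cs the [CellStateSet-class].
#' @param panel character gene ids.
#' @param ratioFloor minimum cell correlation for a defined ratio
#'   (default 0.05).
#' @return list with `geneCorr`, `cellCorr`, `ratio` (NA when
#'   undefined), `nCells`, `nGenes`.
#' @export
correlationDegrees <- function(window, cs, panel, ratioFloor = 0.05) {
  x <- exprValues(cs)[window$cells, panel, drop = FALSE]
  keep <- apply(x, 2L, sd) > 0
  x <- x[, keep, drop = FALSE]
  if (nrow(x) < 3L || ncol(x) < 2L)
    return(list(geneCorr = NA_real_, cellCorr = NA_real_,
                ratio = NA_real_, nCells = nrow(x), nGenes = ncol(x)))
  gc <- cor(x)
  geneCorr <- mean(abs(gc[upper.tri(gc)]))
  keepCells <- apply(x, 1L, sd) > 0
  xc <- x[keepCells, , drop = FALSE]
  cellCorr <- if (nrow(xc) >= 2L) {
    cc <- cor(t(xc))
    mean(cc[upper.tri(cc)])
  } else NA_real_
  ratio <- if (!is.na(cellCorr) && cellCorr > ratioFloor)
    geneCorr / cellCorr else NA_real_
  list(geneCorr = geneCorr, cellCorr = cellCorr, ratio = ratio,
       nCells = nrow(x), nGenes = ncol(x))
}

#' Correlation-degree trajectory over a window series
#'
#' @param windows list from [makePseudotimeWindows()].
#' @param cs the [CellStateSet-class].
#' @param panel character gene ids.
#' @param ratioFloor see [correlationDegrees()].
#' @return data.frame with one row per window: `center`, `scope`,
#'   `gene_corr`, `cell_corr`, `ratio`, `n_cells`.
#' @export
correlationTrajectory <- function(windows, cs, panel,
                                  ratioFloor = 0.05) {
  rows <- lapply(windows, function(w) {
    d <- correlationDegrees(w, cs, panel, ratioFloor)
    data.frame(center = w$center, scope = w$scope,
               gene_corr = d$geneCorr, cell_corr = d$cellCorr,
               ratio = d$ratio, n_cells = length(w$cells))
  })
  do.call(rbind, rows)
}
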