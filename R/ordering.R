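#' Build a CellOrdering from externally supplied pseudotime
#'
#' The landscape, dynamics, network, and burst modules only need the
#' pseudotime (and optionally a branch label) per cell, so orderings
#' produced by other trajectory tools can be plugged in directly. The
#' ordering carries a placeholder single-node tree; operations that need
#' real tree geometry (per-branch window scoping beyond the labels
#' given) treat all cells as one branch unless `branchId` says
#' otherwise.
#'
#' @param cellIds character cell identifiers.
#' @param tau pseudotime values in `[0, 1]` (rescaled if outside).
#' @param branchId optional integer branch label per cell (default 1).
#' @return a [CellOrdering-class].
#' @export
manualOrdering <- function(cellIds, tau, branchId = 1L) {
  m <- length(cellIds)
  stopifnot(length(tau) == m)
  if (max(tau) > 1 || min(tau) < 0) {
    tau <- (tau - min(tau)) / (max(tau) - min(tau))
  }
  branchId <- rep_len(as.integer(branchId), m)
  tree <- new("BackboneTree", nodeCells = 1L,
              nodeCoords = matrix(0, 1, 1),
              edges = matrix(integer(0), 0, 2), rootNode = 1L,
              params = list())
  new("CellOrdering", cellIds = as.character(cellIds),
      edgeId = rep(NA_integer_, m), arcPosition = numeric(m),
      pseudotime = as.numeric(tau), branchId = branchId,
      projectionDist = numeric(m), tree = tree, rootNode = 1L,
      edgeParent = integer(0),
      chainOfEdge = seq_len(max(branchId)))
}

#' Project cells onto the backbone and assign pseudotime
#'
#' Every cell is projected onto the closest point over all tree edges
#' (perpendicular foot clamped to the segment ends; ties broken by the
#' lower edge id). The pseudotime of a cell is the tree path length from
#' the root to its projection, divided by the maximum such length, so the
#' full range is `[0, 1]`. The root is the tree node minimizing the total
#' distance to the `rootHint` cells when hints are given, otherwise the
#' growth start node. Maximal unbranched edge chains are enumerated
#' root-first (children in ascending node id); each cell inherits the
#' chain of the edge carrying its projection as its `branchId`.
#'
#' @param tree a [BackboneTree-class] (a singleton tree yields the
#'   degenerate ordering: all pseudotimes 0, with a warning).
#' @param cs the [CellStateSet-class].
#' @param rootHint optional cell ids or indices of known root (early)
#'   cells.
#' @return a [CellOrdering-class].
#' @export
projectCells <- function(tree, cs, rootHint = NULL) {
  coords <- stateCoords(cs)
  m <- nrow(coords)
  nNodes <- length(tree@nodeCells)
  if (nrow(tree@edges) == 0L) {
    warning("singleton backbone tree: degenerate ordering, ",
            "all pseudotimes set to 0")
    return(new("CellOrdering", cellIds = cellIds(cs),
               edgeId = rep(NA_integer_, m), arcPosition = numeric(m),
               pseudotime = numeric(m), branchId = rep(1L, m),
               projectionDist = .distToAll(tree@nodeCoords[1L, ], coords),
               tree = tree, rootNode = tree@rootNode,
               edgeParent = integer(0), chainOfEdge = integer(0)))
  }
  nE <- nrow(tree@edges)
  bestDist <- rep(Inf, m); bestEdge <- integer(m); bestT <- numeric(m)
  edgeLen <- numeric(nE)
  for (k in seq_len(nE)) {
    a <- tree@nodeCoords[tree@edges[k, 1L], ]
    b <- tree@nodeCoords[tree@edges[k, 2L], ]
    ab <- b - a
    len2 <- sum(ab^2)
    edgeLen[k] <- sqrt(len2)
    diffs <- sweep(coords, 2L, a)
    proj <- as.numeric(diffs %*% ab)
    tt <- if (len2 > 0) pmin(1, pmax(0, proj / len2)) else rep(0, m)
    dd <- sqrt(pmax(0, rowSums(diffs^2) - 2 * tt * proj + tt^2 * len2))
    upd <- dd < bestDist - 1e-15  # strict: ties keep the lower edge id
    bestDist[upd] <- dd[upd]
    bestEdge[upd] <- k
    bestT[upd] <- tt[upd]
  }

  # root selection
  root <- tree@rootNode
  if (!is.null(rootHint)) {
    if (is.character(rootHint)) {
      rootHint <- match(rootHint, cellIds(cs))
      if (anyNA(rootHint)) stop("unknown cell id in rootHint")
    }
    hintCoords <- coords[rootHint, , drop = FALSE]
    tot <- vapply(seq_len(nNodes), function(i)
      sum(.distToAll(tree@nodeCoords[i, ], hintCoords)), numeric(1L))
    root <- which.min(tot)
  }

  # orient the tree from the root; accumulate root path lengths
  adj <- treeAdjacency(tree)
  parent <- rep(NA_integer_, nNodes)
  parentEdge <- rep(NA_integer_, nNodes)
  rootDist <- rep(NA_real_, nNodes)
  rootDist[root] <- 0
  queue <- root
  orderVisited <- root
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    kids <- integer(0); kidEdges <- integer(0)
    for (k in adj[[v]]) {
      w <- setdiff(tree@edges[k, ], v)
      if (is.na(rootDist[w])) { kids <- c(kids, w); kidEdges <- c(kidEdges, k) }
    }
    o <- order(kids)
    kids <- kids[o]; kidEdges <- kidEdges[o]
    for (i in seq_along(kids)) {
      w <- kids[i]; k <- kidEdges[i]
      parent[w] <- v; parentEdge[w] <- k
      rootDist[w] <- rootDist[v] + edgeLen[k]
      queue <- c(queue, w)
      orderVisited <- c(orderVisited, w)
    }
  }
  # per-edge parent endpoint (1 or 2 column of tree@edges)
  edgeParent <- integer(nE)
  for (k in seq_len(nE)) {
    u <- tree@edges[k, 1L]; v <- tree@edges[k, 2L]
    edgeParent[k] <- if (identical(parent[v], u)) 1L else 2L
  }

  # chains are maximal unbranched edge runs: only junction nodes
  # (degree >= 3) break them. A degree-2 root sits inside its chain,
  # so both root-adjacent edges share one chain id.
  deg <- nodeDegrees(tree)
  chainOfEdge <- integer(nE)
  nextChain <- 0L
  rootChain <- 0L
  for (w in orderVisited) {
    if (w == root) next
    k <- parentEdge[w]
    p <- parent[w]
    if (p == root) {
      if (deg[root] >= 3L || rootChain == 0L) {
        nextChain <- nextChain + 1L
        chainOfEdge[k] <- nextChain
        rootChain <- chainOfEdge[k]
      } else {
        chainOfEdge[k] <- rootChain
      }
    } else if (deg[p] >= 3L) {
      nextChain <- nextChain + 1L
      chainOfEdge[k] <- nextChain
    } else {
      chainOfEdge[k] <- chainOfEdge[parentEdge[p]]
    }
  }

  # pseudotime from arc positions measured from the parent end
  arcFromParent <- numeric(m)
  for (k in seq_len(nE)) {
    sel <- bestEdge == k
    if (!any(sel)) next
    tt <- bestT[sel]
    if (edgeParent[k] == 2L) tt <- 1 - tt
    arcFromParent[sel] <- tt * edgeLen[k]
  }
  parentNodeOfEdge <- ifelse(edgeParent == 1L, tree@edges[, 1L],
                             tree@edges[, 2L])
  tauRaw <- rootDist[parentNodeOfEdge[bestEdge]] + arcFromParent
  maxTau <- max(tauRaw)
  tau <- if (maxTau > 0) tauRaw / maxTau else tauRaw

  new("CellOrdering", cellIds = cellIds(cs), edgeId = bestEdge,
      arcPosition = arcFromParent, pseudotime = as.numeric(tau),
      branchId = chainOfEdge[bestEdge],
      projectionDist = as.numeric(bestDist), tree = tree,
      rootNode = as.integer(root), edgeParent = edgeParent,
      chainOfEdge = chainOfEdge)
}
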