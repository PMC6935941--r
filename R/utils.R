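# Internal helpers shared across modules.

# Quantile convention used everywhere in the package: linear interpolation
# between order statistics (stats::quantile type 7, the R default).
.quantileLinear <- function(x, q) as.numeric(quantile(x, q, type = 7L,
                                                      names = FALSE))

# Degrees of the tree nodes.
nodeDegrees <- function(tree) {
  n <- length(tree@nodeCells)
  deg <- integer(n)
  if (nrow(tree@edges)) {
    t1 <- tabulate(tree@edges[, 1L], n)
    t2 <- tabulate(tree@edges[, 2L], n)
    deg <- t1 + t2
  }
  deg
}

# Adjacency list of a BackboneTree.
treeAdjacency <- function(tree) {
  n <- length(tree@nodeCells)
  adj <- vector("list", n)
  e <- tree@edges
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1L]]] <- c(adj[[e[k, 1L]]], k)
    adj[[e[k, 2L]]] <- c(adj[[e[k, 2L]]], k)
  }
  adj
}

# Euclidean distances from one point to all rows of a matrix.
.distToAll <- function(point, coords) {
  sqrt(pmax(0, rowSums(sweep(coords, 2L, point)^2)))
}

# Minimum distance from a point to a polyline given by node coordinates
# and an edge matrix (falls back to node distances when edgeless).
.distToPolyline <- function(point, nodeCoords, edges) {
  best <- min(.distToAll(point, nodeCoords))
  for (k in seq_len(nrow(edges))) {
    a <- nodeCoords[edges[k, 1L], ]
    b <- nodeCoords[edges[k, 2L], ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    tt <- min(1, max(0, sum((point - a) * ab) / len2))
    best <- min(best, sqrt(sum((a + tt * ab - point)^2)))
  }
  best
}

# Single-linkage clusters of points at a distance cutoff (BFS over the
# implied epsilon-graph). Returns an integer cluster id per row.
.singleLinkClusters <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  d <- as.matrix(dist(coords))
  cluster <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (cluster[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    cluster[i] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(d[v, ] <= cutoff & cluster == 0L)
      cluster[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  cluster
}

.checkScalar <- function(x, name, lo = -Inf, hi = Inf,
                         openLo = FALSE, openHi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar")
  bad <- if (openLo) x <= lo else x < lo
  bad <- bad || if (openHi) x >= hi else x > hi
  if (bad)
    stop(sprintf("'%s' = %g is outside its valid range %s%g, %g%s",
                 name, x, if (openLo) "(" else "[", lo, hi,
                 if (openHi) ")" else "]"))
  invisible(x)
}
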