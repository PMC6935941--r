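#' Parameters controlling backbone tree growth
#'
#' Collects the tunables of the super-ring well search into one validated
#' list. Defaults follow the package's standard configuration: the ring
#' radius starts at three kernel bandwidths and grows geometrically until
#' the annulus holds at least `minRingCells` cells, the annulus half-width
#' is one bandwidth, candidate wells need a decision-graph distance of at
#' least half the ring radius, and candidates inside the half-width tube
#' of the existing tree polyline are excluded (this is what removes the
#' well found on the reverse search direction).
#'
#' @param baseRadiusFactor ring base radius, in units of sigma (default 3).
#' @param halfWidthFactor annulus half-width, in units of sigma (default 1).
#' @param minRingCells minimum annulus occupancy (default 10, >= 2).
#' @param radiusGrowth geometric growth factor of the radius grid
#'   (default 1.1).
#' @param deltaMinFactor well threshold on delta, in units of the ring
#'   radius (default 0.5).
#' @param excludeFactor proximity-exclusion distance against the
#'   already-built backbone polyline, in units of the annulus half-width
#'   (default 1). Candidate wells this close to an existing node or
#'   edge are re-discoveries of explored territory — in particular the
#'   well re-found on the reverse search direction — and are dropped;
#'   genuine sibling branches diverge from the polyline and survive.
#' @param mergeFactor link cutoff for merging newly found wells, in units
#'   of the annulus half-width (default 1): wells connected through ring
#'   members by a single-linkage chain at this cutoff are duplicates of
#'   one basin, and only the deepest is kept. Wells on distinct branches
#'   are separated by a gap in the ring and never chain together.
#' @param maxDepth safety cap on the breadth-first recursion depth
#'   (default 50).
#' @param minCellsTotal refuse datasets smaller than this (default 100):
#'   density-based well finding is unreliable on fewer cells.
#' @param wellFilter low-pseudo-potential criterion for well candidates:
#'   `"support"` (default) requires `supportMin` ring members within half
#'   a radius of the candidate (rejects isolated outliers without
#'   penalizing branches of unequal density), `"median"` requires the
#'   candidate's pseudo-potential to lie below the ring median (can
#'   suppress wells on sparser branches), `"none"` keeps the
#'   delta criterion only.
#' @param supportMin minimum local support for `wellFilter = "support"`
#'   (default 5).
#' @param pruneFactor spur-pruning distance, in units of the annulus
#'   half-width (default 1.5): after growth, leaf nodes closer than this
#'   to the polyline of the remaining tree are removed iteratively.
#'   Such spurs are duplicate tracks of an already-covered branch (they
#'   arise when two frontier rings race into the same region); genuine
#'   trajectory ends sit a full step from the rest of the tree. 0
#'   disables pruning.
#' @param contractFactor contraction threshold for adjacent branch
#'   nodes, in units of the step length (default 1): two connected
#'   nodes of degree >= 3 closer than this cannot be resolved as
#'   distinct fate-decision points at the search resolution and are
#'   contracted into the one with the lower pseudo-potential (so a
#'   trifurcation found as two tight bifurcations becomes one
#'   degree-4 node). 0 disables contraction.
#' @return a named list of class `backboneParams`.
#' @export
backboneParams <- function(baseRadiusFactor = 3, halfWidthFactor = 1,
                           minRingCells = 10L, radiusGrowth = 1.1,
                           deltaMinFactor = 0.5, excludeFactor = 1,
                           mergeFactor = 1, maxDepth = 50L,
                           minCellsTotal = 100L,
                           wellFilter = c("support", "median", "none"),
                           supportMin = 5L, pruneFactor = 1.5,
                           contractFactor = 1) {
  wellFilter <- match.arg(wellFilter)
  .checkScalar(supportMin, "supportMin", 1, Inf)
  .checkScalar(pruneFactor, "pruneFactor", 0, Inf)
  .checkScalar(contractFactor, "contractFactor", 0, Inf)
  .checkScalar(baseRadiusFactor, "baseRadiusFactor", 0, Inf, openLo = TRUE)
  .checkScalar(halfWidthFactor, "halfWidthFactor", 0, Inf, openLo = TRUE)
  .checkScalar(minRingCells, "minRingCells", 2, Inf)
  .checkScalar(radiusGrowth, "radiusGrowth", 1, Inf, openLo = TRUE)
  .checkScalar(deltaMinFactor, "deltaMinFactor", 0, Inf)
  .checkScalar(excludeFactor, "excludeFactor", 0, Inf)
  .checkScalar(mergeFactor, "mergeFactor", 0, Inf)
  .checkScalar(maxDepth, "maxDepth", 1, Inf)
  structure(list(baseRadiusFactor = baseRadiusFactor,
                 halfWidthFactor = halfWidthFactor,
                 minRingCells = as.integer(minRingCells),
                 radiusGrowth = radiusGrowth,
                 deltaMinFactor = deltaMinFactor,
                 excludeFactor = excludeFactor,
                 mergeFactor = mergeFactor,
                 maxDepth = as.integer(maxDepth),
                 minCellsTotal = as.integer(minCellsTotal),
                 wellFilter = wellFilter,
                 supportMin = as.integer(supportMin),
                 pruneFactor = pruneFactor,
                 contractFactor = contractFactor),
            class = "backboneParams")
}

#' Adaptive step length (super-ring radius) at a center point
#'
#' Returns the smallest radius r >= baseRadius, searched on the geometric
#' grid r = baseRadius * growth^k, whose annulus [r - w, r + w] contains at
#' least `minRingCells` cells. When no radius up to the data extent
#' qualifies the boundary signal `NA` is returned; tree growth treats that
#' as branch termination.
#'
#' @param center numeric coordinate vector (a point in the distance space).
#' @param cs a [CellStateSet-class].
#' @param context a [DistanceContext-class].
#' @param minRingCells required annulus occupancy (>= 2).
#' @param baseRadius initial radius (default 3 sigma).
#' @param halfWidth annulus half-width (default sigma; must stay below the
#'   radius).
#' @param radiusGrowth geometric grid factor (default 1.1).
#' @return the selected radius, or `NA_real_` (boundary signal).
#' @export
adaptiveStep <- function(center, cs, context, minRingCells = 10L,
                         baseRadius = 3 * context@sigma,
                         halfWidth = context@sigma,
                         radiusGrowth = 1.1) {
  .checkScalar(minRingCells, "minRingCells", 2, Inf)
  .checkScalar(baseRadius, "baseRadius", 0, Inf, openLo = TRUE)
  if (halfWidth >= baseRadius)
    stop("halfWidth must be smaller than the ring radius")
  d <- .distToAll(center, stateCoords(cs))
  maxd <- max(d)
  r <- baseRadius
  while (r - halfWidth <= maxd) {
    if (sum(abs(d - r) <= halfWidth) >= minRingCells) return(r)
    r <- r * radiusGrowth
  }
  NA_real_
}

#' Find pseudo-potential wells on one super-ring
#'
#' Restricts the pseudo-potential field to the annulus members, computes
#' the decision-graph distance delta on that subset, and returns the
#' members that combine a relatively low pseudo-potential with a
#' relatively large delta (at least `deltaMin`), sorted by ascending
#' pseudo-potential. These are the well centers (density peaks) the tree
#' growth links to. The low-pseudo-potential side of the criterion is
#' pluggable (`wellFilter`): the default requires the candidate to carry
#' local support (at least `supportMin` ring members within half a
#' radius), which rejects isolated outliers while still detecting wells
#' on branches much sparser than their siblings; `"median"` instead
#' requires the candidate to lie below the ring's median
#' pseudo-potential.
#'
#' @param center coordinate vector of the ring center.
#' @param radius ring radius (the step length).
#' @param cs a [CellStateSet-class].
#' @param field a [PseudoPotentialField-class].
#' @param halfWidth annulus half-width (default sigma).
#' @param deltaMin threshold on delta (default radius / 2).
#' @param wellFilter `"support"`, `"median"`, or `"none"` (see
#'   [backboneParams()]).
#' @param supportMin minimum member count within radius/2 of a candidate
#'   for `"support"` (default 5).
#' @param mergeLink link cutoff (distance units) for the
#'   density-connectivity merge of candidate wells; defaults to the
#'   half-width. A uniform ring sampled densely relative to this cutoff
#'   is one connected piece and yields at most one well; sparse uniform
#'   sampling can leave fluctuation gaps that the downstream tree
#'   growth removes by exclusion and spur pruning instead.
#' @return integer cell indices of the wells (possibly empty), sorted
#'   by ascending pseudo-potential, one per density-connected piece of
#'   the ring.
#' @export
findWellsOnRing <- function(center, radius, cs, field,
                            halfWidth = kernelSigma(field),
                            deltaMin = radius / 2,
                            wellFilter = c("support", "median", "none"),
                            supportMin = 5L, mergeLink = halfWidth) {
  wellFilter <- match.arg(wellFilter)
  coords <- stateCoords(cs)
  d <- .distToAll(center, coords)
  members <- which(abs(d - radius) <= halfWidth)
  if (length(members) <= 1L) return(integer(0))
  e <- field@eTilde[members]
  delta <- computeDelta(members, field, cs)
  ok <- delta >= deltaMin
  memberCoords <- coords[members, , drop = FALSE]
  if (wellFilter == "median") {
    ok <- ok & e < median(e)
  } else if (wellFilter == "support") {
    support <- vapply(which(ok), function(i)
      sum(.distToAll(memberCoords[i, ], memberCoords) <= radius / 2),
      integer(1L))
    ok[which(ok)] <- support >= supportMin
  }
  wells <- members[ok]
  wells <- wells[order(e[ok], wells)]
  if (length(wells) > 1L) {
    # one well per density-connected piece of the ring: members whose
    # gaps stay below the link cutoff belong to the same basin, and
    # only its deepest candidate is kept
    clusters <- .singleLinkClusters(memberCoords, mergeLink)
    wellCluster <- clusters[match(wells, members)]
    wells <- wells[!duplicated(wellCluster)]
  }
  wells
}

#' Grow the backbone tree by recursive well search on super-rings
#'
#' Breadth-first growth: starting from the global minimum-pseudo-potential
#' cell (or `start`), each frontier node gets an adaptive-step super-ring;
#' wells found on the ring are linked to it as child nodes after two
#' filters that keep the tree acyclic and noise-robust: candidates within
#' one step length of any *existing* node are excluded (in particular the
#' well re-found on the reverse search direction), and any two new wells
#' closer than the step length are merged by discarding the one with the
#' larger pseudo-potential. A branch terminates when no wells survive or
#' when the annulus can no longer be filled (data boundary).
#'
#' @param cs a [CellStateSet-class] with at least `minCellsTotal` cells.
#' @param field a [PseudoPotentialField-class].
#' @param start optional starting cell (index or cell id); defaults to the
#'   cell with the global minimum pseudo-potential.
#' @param params a [backboneParams()] list.
#' @return a [BackboneTree-class].
#' @export
growBackboneTree <- function(cs, field, start = NULL,
                             params = backboneParams()) {
  stopifnot(inherits(params, "backboneParams"))
  m <- nCells(cs)
  if (m < params$minCellsTotal)
    stop("only ", m, " cells: fewer than ", params$minCellsTotal,
         " cells makes density-based well finding unreliable; ",
         "refusing to grow a backbone")
  coords <- stateCoords(cs)
  sigma <- kernelSigma(field)
  if (is.null(start)) {
    start <- order(field@eTilde, seq_len(m))[1L]
  } else if (is.character(start)) {
    start <- match(start, cellIds(cs))
    if (is.na(start)) stop("start cell id not found")
  }
  start <- as.integer(start)

  nodeCells <- start
  startCell <- start
  stepLengths <- NA_real_  # per node: the radius of the ring that found it
  edges <- matrix(integer(0), 0L, 2L)
  queue <- list(list(node = 1L, depth = 0L))
  while (length(queue)) {
    item <- queue[[1L]]; queue <- queue[-1L]
    centerNode <- item$node
    center <- coords[nodeCells[centerNode], ]
    r <- adaptiveStep(center, cs, field@context,
                      minRingCells = params$minRingCells,
                      baseRadius = params$baseRadiusFactor * sigma,
                      halfWidth = params$halfWidthFactor * sigma,
                      radiusGrowth = params$radiusGrowth)
    if (is.na(r)) next  # boundary: branch terminates
    wells <- findWellsOnRing(center, r, cs, field,
                             halfWidth = params$halfWidthFactor * sigma,
                             deltaMin = params$deltaMinFactor * r,
                             wellFilter = params$wellFilter,
                             supportMin = params$supportMin,
                             mergeLink = params$mergeFactor *
                               params$halfWidthFactor * sigma)
    if (!length(wells)) next
    # exclude candidates inside the tube of the existing backbone (this
    # removes the well re-found on the reverse search direction); the
    # ring's own center cannot trigger it, every candidate being about
    # one radius away
    exclDist <- params$excludeFactor * params$halfWidthFactor * sigma
    nodeMat <- coords[nodeCells, , drop = FALSE]
    keep <- vapply(wells, function(w)
      .distToPolyline(coords[w, ], nodeMat, edges) >= exclDist,
      logical(1L))
    wells <- wells[keep]
    # drop wells that already are nodes
    kept <- setdiff(wells, nodeCells)
    for (w in kept) {
      nodeCells <- c(nodeCells, w)
      stepLengths <- c(stepLengths, r)
      newNode <- length(nodeCells)
      edges <- rbind(edges, c(centerNode, newNode))
      if (item$depth + 1L < params$maxDepth)
        queue <- c(queue, list(list(node = newNode,
                                    depth = item$depth + 1L)))
    }
  }
  storage.mode(edges) <- "integer"
  # spur pruning: drop leaves that duplicate already-covered territory
  if (params$pruneFactor > 0 && nrow(edges) > 1L) {
    pruneDist <- params$pruneFactor * params$halfWidthFactor * sigma
    repeat {
      n <- length(nodeCells)
      deg <- tabulate(edges, n)
      pruned <- FALSE
      for (leaf in which(deg == 1L)) {
        if (leaf == 1L) next  # never prune the growth start
        others <- setdiff(seq_len(n), leaf)
        keepEdges <- edges[edges[, 1L] != leaf & edges[, 2L] != leaf, ,
                           drop = FALSE]
        remap <- match(keepEdges, others)
        dim(remap) <- dim(keepEdges)
        d <- .distToPolyline(coords[nodeCells[leaf], ],
                             coords[nodeCells[others], , drop = FALSE],
                             remap)
        if (d < pruneDist) {
          nodeCells <- nodeCells[others]
          stepLengths <- stepLengths[others]
          edges <- remap
          pruned <- TRUE
          break
        }
      }
      if (!pruned || nrow(edges) == 0L) break
    }
  }
  # contract adjacent branch nodes closer than the step length: they are
  # one fate-decision point below the search resolution
  if (params$contractFactor > 0 && nrow(edges) > 0L) {
    repeat {
      n <- length(nodeCells)
      deg <- tabulate(edges, n)
      done <- TRUE
      for (k in seq_len(nrow(edges))) {
        u <- edges[k, 1L]; v <- edges[k, 2L]
        if (deg[u] < 3L || deg[v] < 3L) next
        len <- sqrt(sum((coords[nodeCells[u], ] -
                           coords[nodeCells[v], ])^2))
        step <- max(stepLengths[c(u, v)], na.rm = TRUE)
        if (!is.finite(step)) step <- 3 * sigma
        if (len >= params$contractFactor * step) next
        # keep the deeper well (lower pseudo-potential)
        keepN <- if (field@eTilde[nodeCells[u]] <=
                       field@eTilde[nodeCells[v]]) u else v
        dropN <- if (keepN == u) v else u
        if (nodeCells[dropN] == startCell)
          startCell <- nodeCells[keepN]
        edges <- edges[-k, , drop = FALSE]
        edges[edges == dropN] <- keepN
        others <- setdiff(seq_len(n), dropN)
        remap <- match(edges, others); dim(remap) <- dim(edges)
        edges <- remap
        nodeCells <- nodeCells[others]
        stepLengths <- stepLengths[others]
        done <- FALSE
        break
      }
      if (done) break
    }
    storage.mode(edges) <- "integer"
  }
  p <- unclass(params)
  p$stepLengths <- stepLengths
  new("BackboneTree", nodeCells = as.integer(nodeCells),
      nodeCoords = coords[nodeCells, , drop = FALSE],
      edges = edges, rootNode = match(startCell, nodeCells),
      params = p)
}

#' Refine backbone edges through local density ridges
#'
#' Subdivides each edge at `nSubdivisions` interior points and replaces
#' every interior point by the highest-density cell within `halfWidth` of
#' it, so straight edges bend onto the data ridge. Interior points with no
#' nearby cell, duplicates, and points that coincide with existing nodes
#' are dropped. Leaves and topology are unchanged; only edges are
#' re-articulated.
#'
#' @param tree a [BackboneTree-class].
#' @param field the [PseudoPotentialField-class] used to rank candidates.
#' @param cs the [CellStateSet-class].
#' @param nSubdivisions interior points per edge (0 returns the tree
#'   unchanged).
#' @param halfWidth candidate search radius around each interior point
#'   (default sigma).
#' @return a refined [BackboneTree-class].
#' @export
refineBackboneTree <- function(tree, field, cs, nSubdivisions = 3L,
                               halfWidth = kernelSigma(field)) {
  nSubdivisions <- as.integer(nSubdivisions)
  if (nSubdivisions <= 0L || nrow(tree@edges) == 0L) return(tree)
  coords <- stateCoords(cs)
  nodeCells <- tree@nodeCells
  newEdges <- matrix(integer(0), 0L, 2L)
  for (k in seq_len(nrow(tree@edges))) {
    u <- tree@edges[k, 1L]; v <- tree@edges[k, 2L]
    a <- tree@nodeCoords[u, ]; b <- tree@nodeCoords[v, ]
    path <- u
    for (i in seq_len(nSubdivisions)) {
      p <- a + (b - a) * i / (nSubdivisions + 1)
      d <- .distToAll(p, coords)
      cand <- which(d <= halfWidth)
      cand <- setdiff(cand, nodeCells)
      if (!length(cand)) next
      best <- cand[which.max(field@rho[cand])]
      nodeCells <- c(nodeCells, best)
      path <- c(path, length(nodeCells))
    }
    path <- c(path, v)
    for (i in seq_len(length(path) - 1L))
      newEdges <- rbind(newEdges, c(path[i], path[i + 1L]))
  }
  storage.mode(newEdges) <- "integer"
  new("BackboneTree", nodeCells = as.integer(nodeCells),
      nodeCoords = coords[nodeCells, , drop = FALSE],
      edges = newEdges, rootNode = tree@rootNode, params = tree@params)
}
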