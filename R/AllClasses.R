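#' @import methods
#' @importFrom stats dist median prcomp quantile rnorm runif rgamma rbinom
#'   cor var sd setNames
#' @importFrom Rcpp sourceCpp
#' @useDynLib scLandscape, .registration = TRUE
NULL

#' CellStateSet: a cells-by-genes expression matrix with identifiers
#'
#' The central data container of the package. Rows are cells, columns are
#' genes; values are nonnegative expression levels in whatever units the
#' input provides (counts, FPKM, log-normalized values, ...). A second,
#' optional coordinate matrix (`reduced`) holds a low-dimensional embedding
#' (e.g. principal components) used for all *distance* computations, while
#' the full gene space is retained for network and bursting analyses.
#'
#' @slot values numeric matrix, cells x genes, nonnegative, finite, with
#'   unique row (cell) and column (gene) names.
#' @slot reduced numeric matrix, cells x d, the coordinates used for
#'   distances when non-empty (0 columns means "use `values`").
#'
#' @seealso [CellStateSet()], [preprocessCells()], [deriveSigma()]
#' @export
setClass("CellStateSet",
  representation(values = "matrix", reduced = "matrix"),
  prototype(values = matrix(numeric(0), 0, 0),
            reduced = matrix(numeric(0), 0, 0))
)

setValidity("CellStateSet", function(object) {
  v <- object@values
  msg <- character(0)
  if (!is.numeric(v)) msg <- c(msg, "'values' must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must carry cell (row) and gene (column) names")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, "duplicate cell ids")
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, "duplicate gene ids")
  }
  if (length(v)) {
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      ij <- arrayInd(bad[1L], dim(v))
      msg <- c(msg, sprintf(
        "negative or non-finite value at cell '%s', gene '%s'",
        rownames(v)[ij[1L]], colnames(v)[ij[2L]]))
    }
  }
  if (nrow(object@reduced) > 0L && nrow(object@reduced) != nrow(v))
    msg <- c(msg, "'reduced' must have one row per cell")
  if (length(msg)) msg else TRUE
})

#' DistanceContext: metric and kernel bandwidth for the cell state space
#'
#' @slot metric distance metric name (only "euclidean" is implemented).
#' @slot sigma positive Gaussian kernel bandwidth, in distance units.
#' @slot sigmaQuantile the quantile of all pairwise distances that `sigma`
#'   was derived from (NA when `sigma` was user-overridden).
#' @export
setClass("DistanceContext",
  representation(metric = "character", sigma = "numeric",
                 sigmaQuantile = "numeric"),
  prototype(metric = "euclidean", sigma = NA_real_,
            sigmaQuantile = NA_real_)
)

setValidity("DistanceContext", function(object) {
  if (!identical(object@metric, "euclidean"))
    return("only the 'euclidean' metric is implemented")
  if (!is.na(object@sigma) && object@sigma <= 0)
    return("sigma must be positive")
  TRUE
})

#' PseudoPotentialField: per-cell local density and pseudo-potential
#'
#' The pseudo-potential of a cell is the negative log of a Gaussian-kernel
#' local density, rho(x) = sum_y exp(-d(x,y)^2 / (2 sigma^2)) (the self
#' term contributes 1, so rho >= 1 and the pseudo-potential is <= 0).
#'
#' @slot rho per-cell local density (>= 1).
#' @slot eTilde per-cell pseudo-potential, -log(rho).
#' @slot context the [DistanceContext-class] used.
#' @export
setClass("PseudoPotentialField",
  representation(rho = "numeric", eTilde = "numeric",
                 context = "DistanceContext")
)

setValidity("PseudoPotentialField", function(object) {
  if (length(object@rho) != length(object@eTilde))
    return("rho and eTilde must have equal length")
  if (length(object@rho) && any(object@rho < 1 - 1e-9))
    return("rho must be >= 1 (self term)")
  if (length(object@rho) &&
      max(abs(object@eTilde + log(object@rho))) > 1e-8)
    return("eTilde must equal -log(rho)")
  TRUE
})

#' BackboneTree: the tree of pseudo-potential well centers
#'
#' Nodes are actual cells (well centers found on super-rings, plus the
#' starting cell); edges link each well to the ring center that found it.
#' The tree is connected and acyclic by construction.
#'
#' @slot nodeCells integer indices of the cells serving as nodes.
#' @slot nodeCoords node coordinates in the distance space (nodes x d).
#' @slot edges integer matrix with two columns (node indices, unordered).
#' @slot rootNode index (into nodes) of the growth start node.
#' @slot params list of growth parameters (step rule, thresholds, ...).
#' @export
setClass("BackboneTree",
  representation(nodeCells = "integer", nodeCoords = "matrix",
                 edges = "matrix", rootNode = "integer", params = "list"),
  prototype(edges = matrix(integer(0), 0, 2), params = list())
)

setValidity("BackboneTree", function(object) {
  n <- length(object@nodeCells)
  if (nrow(object@nodeCoords) != n)
    return("one coordinate row per node required")
  e <- object@edges
  if (n > 0 && nrow(e) != n - 1L)
    return("a tree must satisfy |edges| = |nodes| - 1")
  if (nrow(e) && (any(e < 1L) || any(e > n)))
    return("edge endpoints out of range")
  if (n > 1L) {
    # connectivity check by breadth-first sweep
    adj <- vector("list", n)
    for (k in seq_len(nrow(e))) {
      adj[[e[k, 1L]]] <- c(adj[[e[k, 1L]]], e[k, 2L])
      adj[[e[k, 2L]]] <- c(adj[[e[k, 2L]]], e[k, 1L])
    }
    seen <- logical(n); seen[1L] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    if (!all(seen)) return("tree is not connected")
  }
  TRUE
})

#' CellOrdering: projection of every cell onto the backbone, with pseudotime
#'
#' Each cell is projected onto the closest point of the backbone tree; its
#' pseudotime is the path length from the root to that projection, scaled
#' so the full range is `[0, 1]`. `branchId` indexes the maximal unbranched
#' edge chain (enumerated root-first, children in ascending node id) that
#' carries the projection: one chain = one candidate cell type.
#'
#' @slot cellIds character cell identifiers.
#' @slot edgeId integer index of the edge carrying each projection.
#' @slot arcPosition distance of the projection from the edge's parent end.
#' @slot pseudotime per-cell pseudotime in `[0, 1]`.
#' @slot branchId integer chain index per cell.
#' @slot projectionDist distance from each cell to its projection.
#' @slot tree the [BackboneTree-class] projected onto.
#' @slot rootNode the tree node used as pseudotime origin.
#' @slot edgeParent for each tree edge, which endpoint is root-proximal.
#' @slot chainOfEdge integer chain index per tree edge.
#' @export
setClass("CellOrdering",
  representation(cellIds = "character", edgeId = "integer",
                 arcPosition = "numeric", pseudotime = "numeric",
                 branchId = "integer", projectionDist = "numeric",
                 tree = "BackboneTree", rootNode = "integer",
                 edgeParent = "integer", chainOfEdge = "integer")
)

setValidity("CellOrdering", function(object) {
  m <- length(object@cellIds)
  if (length(object@pseudotime) != m || length(object@branchId) != m)
    return("per-cell slots must have one entry per cell")
  tau <- object@pseudotime
  if (m && (min(tau) < -1e-12 || max(tau) > 1 + 1e-12))
    return("pseudotime must lie in [0, 1]")
  TRUE
})

#' TransitionGraph: the pseudotime-weighted random-walk graph over cells
#'
#' Directed edges alpha -> beta carry weight W0 * exp(-chi * (tau_alpha -
#' tau_beta)): moves toward larger pseudotime are up-weighted. Conditional
#' move probabilities are relative out-link weights, and the stationary
#' visit distribution is the fixed point of the teleported master equation.
#'
#' @slot from,to integer cell indices per directed edge.
#' @slot weight per-edge weight W.
#' @slot conditional per-edge conditional probability p(from -> to)
#'   (empty until [conditionalProbabilities()] is called).
#' @slot stationary per-cell stationary visit probability (empty until
#'   [stationaryDistribution()] is called).
#' @slot nCells number of cells.
#' @slot W0,chi,epsilon graph parameters (base weight, pseudotime
#'   sensitivity, teleportation rate).
#' @slot kNeighbors neighborhood size used for the support.
#' @slot teleport "out-weight" (as printed in the source formula) or
#'   "in-weight".
#' @export
setClass("TransitionGraph",
  representation(from = "integer", to = "integer", weight = "numeric",
                 conditional = "numeric", stationary = "numeric",
                 nCells = "integer", W0 = "numeric", chi = "numeric",
                 epsilon = "numeric", kNeighbors = "integer",
                 teleport = "character"),
  prototype(conditional = numeric(0), stationary = numeric(0),
            epsilon = NA_real_, teleport = "out-weight")
)

setValidity("TransitionGraph", function(object) {
  ne <- length(object@from)
  if (length(object@to) != ne || length(object@weight) != ne)
    return("from/to/weight must have equal length")
  if (ne && any(object@weight <= 0))
    return("weights must be positive")
  if (length(object@conditional) &&
      length(object@conditional) != ne)
    return("conditional must align with edges")
  if (length(object@stationary)) {
    if (length(object@stationary) != object@nCells)
      return("stationary must have one entry per cell")
    if (abs(sum(object@stationary) - 1) > 1e-9)
      return("stationary must sum to 1")
    if (any(object@stationary <= 0))
      return("stationary entries must be positive (teleportation)")
  }
  TRUE
})

#' LandscapeSurface: the rendered quantitative developmental landscape
#'
#' Cells are embedded in 2-D, each grid point takes the potential of its
#' nearest embedded cell (nearest-neighbor interpolation), and the grid is
#' then smoothed with a Gaussian kernel. The backbone tree is carried
#' through the same embedding as an overlay polyline.
#'
#' @slot embedding cells x 2 coordinates.
#' @slot gridX,gridY grid axis coordinates.
#' @slot values smoothed potential surface (length(gridY) x length(gridX)).
#' @slot nnValues the pre-smoothing nearest-neighbor surface.
#' @slot smoothingBandwidth Gaussian bandwidth in grid cells.
#' @slot backboneNodes embedded tree node coordinates (nodes x 2).
#' @slot backboneEdges the tree's edge matrix.
#' @export
setClass("LandscapeSurface",
  representation(embedding = "matrix", gridX = "numeric", gridY = "numeric",
                 values = "matrix", nnValues = "matrix",
                 smoothingBandwidth = "numeric", backboneNodes = "matrix",
                 backboneEdges = "matrix")
)

#' CellTypeAssignment: branch-level cell types and well-level subtypes
#'
#' Every maximal unbranched chain of the backbone is one cell type; every
#' potential well along a chain (detected on the smoothed potential
#' profile) is one cell subtype.
#'
#' @slot typeId integer type per cell (equals the ordering's branchId).
#' @slot subtypeId integer subtype within type (NA until wells detected).
#' @slot nTypes number of types (chains).
#' @export
setClass("CellTypeAssignment",
  representation(typeId = "integer", subtypeId = "integer",
                 nTypes = "integer")
)

#' CellTypeDynamics: transition, exit, and fate probabilities of cell types
#'
#' Built from the stationary link visit rates q(alpha -> beta) =
#' p_alpha * p(alpha -> beta). The type-to-type transition probability
#' sums link rates from type i into type j (j != i); the exit probability
#' sums all links leaving i; fate_i = 1 - exit_i.
#'
#' @slot qMatrix type x type transition probabilities (diagonal 0).
#' @slot qExit per-type exit probability.
#' @slot fate per-type fate probability, 1 - qExit.
#' @slot internalFlux per-type within-type link rate mass.
#' @export
setClass("CellTypeDynamics",
  representation(qMatrix = "matrix", qExit = "numeric", fate = "numeric",
                 internalFlux = "numeric")
)

setValidity("CellTypeDynamics", function(object) {
  k <- length(object@qExit)
  if (!all(dim(object@qMatrix) == c(k, k)))
    return("qMatrix must be nTypes x nTypes")
  if (length(object@fate) != k)
    return("fate must have one entry per type")
  if (any(object@fate < -1e-9 | object@fate > 1 + 1e-9))
    return("fate probabilities must lie in [0, 1]")
  if (max(abs(object@fate - (1 - object@qExit))) > 1e-12)
    return("fate must equal 1 - qExit")
  TRUE
})
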