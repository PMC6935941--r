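#' Construct a CellStateSet
#'
#' @param values numeric cells x genes matrix with row and column names, or
#'   an object inheriting from `SummarizedExperiment` (genes in rows, the
#'   first assay is transposed into cells-in-rows orientation).
#' @param reduced optional cells x d coordinate matrix used for distance
#'   computations (defaults to none: distances use `values`).
#' @return a validated [CellStateSet-class].
#' @examples
#' m <- matrix(c(0, 1, 2, 3, 4, 5), 3, 2, byrow = TRUE,
#'             dimnames = list(paste0("c", 1:3), c("gA", "gB")))
#' cs <- CellStateSet(m)
#' nCells(cs); nGenes(cs)
#' @export
CellStateSet <- function(values, reduced = NULL) {
  if (inherits(values, "SummarizedExperiment")) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
      stop("the SummarizedExperiment package is required for this input")
    values <- t(SummarizedExperiment::assay(values, 1L))
    values <- as.matrix(values)
  }
  if (is.data.frame(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(reduced)) reduced <- matrix(numeric(0), 0L, 0L)
  new("CellStateSet", values = values, reduced = as.matrix(reduced))
}

#' Accessors for CellStateSet
#'
#' `exprValues()` returns the cells x genes expression matrix;
#' `stateCoords()` the coordinates used for distance computations (the
#' reduced embedding when present, otherwise the expression matrix);
#' `cellIds()`/`geneIds()` the identifiers; `nCells()`/`nGenes()` the
#' dimensions.
#'
#' @param x a [CellStateSet-class].
#' @name CellStateSet-accessors
NULL

#' @rdname CellStateSet-accessors
#' @export
setMethod("exprValues", "CellStateSet", function(x) x@values)

#' @rdname CellStateSet-accessors
#' @export
setMethod("stateCoords", "CellStateSet", function(x) {
  if (ncol(x@reduced) > 0L) x@reduced else x@values
})

#' @rdname CellStateSet-accessors
#' @export
setMethod("cellIds", "CellStateSet", function(x) rownames(x@values))

#' @rdname CellStateSet-accessors
#' @export
setMethod("geneIds", "CellStateSet", function(x) colnames(x@values))

#' @rdname CellStateSet-accessors
#' @export
setMethod("nCells", "CellStateSet", function(x) nrow(x@values))

#' @rdname CellStateSet-accessors
#' @export
setMethod("nGenes", "CellStateSet", function(x) ncol(x@values))

setMethod("show", "CellStateSet", function(object) {
  cat("CellStateSet:", nCells(object), "cells x", nGenes(object), "genes\n")
  if (ncol(object@reduced) > 0L)
    cat("  distance space:", ncol(object@reduced), "reduced dimensions\n")
})

#' Pseudo-potential field accessors
#'
#' @param x a [PseudoPotentialField-class].
#' @name pseudoPotential-accessors
NULL

#' @rdname pseudoPotential-accessors
#' @export
setMethod("pseudoPotential", "PseudoPotentialField", function(x) x@eTilde)

#' @rdname pseudoPotential-accessors
#' @export
setMethod("localDensity", "PseudoPotentialField", function(x) x@rho)

#' Kernel bandwidth of a DistanceContext
#'
#' @param x a [DistanceContext-class] or [PseudoPotentialField-class].
#' @name kernelSigma
NULL

#' @rdname kernelSigma
#' @export
setMethod("kernelSigma", "DistanceContext", function(x) x@sigma)

#' @rdname kernelSigma
#' @export
setMethod("kernelSigma", "PseudoPotentialField",
          function(x) x@context@sigma)

setMethod("show", "DistanceContext", function(object) {
  cat("DistanceContext:", object@metric, "metric, sigma =",
      format(object@sigma, digits = 4),
      if (!is.na(object@sigmaQuantile))
        sprintf("(quantile %.3g)", object@sigmaQuantile) else "", "\n")
})

setMethod("show", "PseudoPotentialField", function(object) {
  cat("PseudoPotentialField over", length(object@rho), "cells;",
      "pseudo-potential range",
      paste(format(range(object@eTilde), digits = 4), collapse = " .. "),
      "\n")
})

#' BackboneTree accessors
#'
#' `treeNodes()` returns a data.frame of node ids, source cell indices and
#' coordinates; `treeEdges()` the two-column edge matrix; `branchPoints()`
#' the indices of nodes with degree >= 3 (fate decision points).
#'
#' @param x a [BackboneTree-class].
#' @name BackboneTree-accessors
NULL

#' @rdname BackboneTree-accessors
#' @export
setMethod("treeNodes", "BackboneTree", function(x) {
  data.frame(node = seq_along(x@nodeCells), cell = x@nodeCells,
             x@nodeCoords, check.names = FALSE)
})

#' @rdname BackboneTree-accessors
#' @export
setMethod("treeEdges", "BackboneTree", function(x) x@edges)

#' @rdname BackboneTree-accessors
#' @export
setMethod("branchPoints", "BackboneTree", function(x) {
  deg <- nodeDegrees(x)
  which(deg >= 3L)
})

setMethod("show", "BackboneTree", function(object) {
  deg <- nodeDegrees(object)
  cat("BackboneTree:", length(object@nodeCells), "nodes,",
      nrow(object@edges), "edges,",
      sum(deg >= 3L), "branch point(s),",
      sum(deg <= 1L), "leaf/leaves\n")
})

#' CellOrdering accessors
#'
#' @param x a [CellOrdering-class].
#' @name CellOrdering-accessors
NULL

#' @rdname CellOrdering-accessors
#' @export
setMethod("pseudotime", "CellOrdering", function(x)
  setNames(x@pseudotime, x@cellIds))

#' @rdname CellOrdering-accessors
#' @export
setMethod("branchIds", "CellOrdering", function(x)
  setNames(x@branchId, x@cellIds))

#' Convert a CellOrdering to a data.frame
#'
#' @param x a [CellOrdering-class].
#' @param row.names,optional,... passed through for compatibility.
#' @export
as.data.frame.CellOrdering <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(cell_id = x@cellIds, edge_id = x@edgeId,
             arc_position = x@arcPosition, pseudotime = x@pseudotime,
             branch_id = x@branchId, projection_dist = x@projectionDist,
             stringsAsFactors = FALSE)
}

setMethod("show", "CellOrdering", function(object) {
  cat("CellOrdering:", length(object@cellIds), "cells on",
      max(object@chainOfEdge, 0L), "branch(es); pseudotime in [",
      format(min(object@pseudotime), digits = 3), ",",
      format(max(object@pseudotime), digits = 3), "]\n")
})

#' TransitionGraph accessors
#'
#' @param x a [TransitionGraph-class].
#' @name TransitionGraph-accessors
NULL

#' @rdname TransitionGraph-accessors
#' @export
setMethod("stationaryProbs", "TransitionGraph", function(x) {
  if (!length(x@stationary))
    stop("stationary distribution not computed yet; ",
         "call stationaryDistribution()")
  x@stationary
})

#' @rdname TransitionGraph-accessors
#' @export
setMethod("conditionalProbs", "TransitionGraph", function(x) {
  if (!length(x@conditional))
    stop("conditional probabilities not computed yet; ",
         "call conditionalProbabilities()")
  data.frame(from = x@from, to = x@to, p = x@conditional)
})

setMethod("show", "TransitionGraph", function(object) {
  cat("TransitionGraph:", object@nCells, "cells,", length(object@from),
      "directed edges (chi =", object@chi, ", k =", object@kNeighbors,
      ")\n")
  if (length(object@stationary))
    cat("  stationary distribution converged (epsilon =",
        object@epsilon, ")\n")
})

setMethod("show", "LandscapeSurface", function(object) {
  cat("LandscapeSurface:", nrow(object@embedding), "cells on a",
      length(object@gridY), "x", length(object@gridX), "grid, bandwidth",
      object@smoothingBandwidth, "grid cells\n")
})

#' CellTypeAssignment accessors
#'
#' @param x a [CellTypeAssignment-class].
#' @name CellTypeAssignment-accessors
NULL

#' @rdname CellTypeAssignment-accessors
#' @export
setMethod("cellTypes", "CellTypeAssignment", function(x) x@typeId)

#' @rdname CellTypeAssignment-accessors
#' @export
setMethod("cellSubtypes", "CellTypeAssignment", function(x) x@subtypeId)

setMethod("show", "CellTypeAssignment", function(object) {
  cat("CellTypeAssignment:", length(object@typeId), "cells,",
      object@nTypes, "type(s)")
  if (!all(is.na(object@subtypeId)))
    cat(",", length(unique(paste(object@typeId, object@subtypeId))),
        "subtype(s)")
  cat("\n")
})

#' CellTypeDynamics accessors
#'
#' @param x a [CellTypeDynamics-class].
#' @name CellTypeDynamics-accessors
NULL

#' @rdname CellTypeDynamics-accessors
#' @export
setMethod("transitionMatrix", "CellTypeDynamics", function(x) x@qMatrix)

#' @rdname CellTypeDynamics-accessors
#' @export
setMethod("fateProbs", "CellTypeDynamics", function(x) x@fate)

#' @rdname CellTypeDynamics-accessors
#' @export
setMethod("exitProbs", "CellTypeDynamics", function(x) x@qExit)

setMethod("show", "CellTypeDynamics", function(object) {
  cat("CellTypeDynamics over", length(object@fate), "cell type(s)\n")
  cat("  fate:", paste(format(object@fate, digits = 3), collapse = ", "),
      "\n")
})
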