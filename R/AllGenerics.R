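#' @rdname CellStateSet-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname CellStateSet-accessors
#' @export
setGeneric("stateCoords", function(x) standardGeneric("stateCoords"))

#' @rdname CellStateSet-accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname CellStateSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname CellStateSet-accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname CellStateSet-accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname pseudoPotential-accessors
#' @export
setGeneric("pseudoPotential", function(x) standardGeneric("pseudoPotential"))

#' @rdname pseudoPotential-accessors
#' @export
setGeneric("localDensity", function(x) standardGeneric("localDensity"))

#' @rdname kernelSigma
#' @export
setGeneric("kernelSigma", function(x) standardGeneric("kernelSigma"))

#' @rdname BackboneTree-accessors
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))

#' @rdname BackboneTree-accessors
#' @export
setGeneric("treeEdges", function(x) standardGeneric("treeEdges"))

#' @rdname BackboneTree-accessors
#' @export
setGeneric("branchPoints", function(x) standardGeneric("branchPoints"))

#' @rdname CellOrdering-accessors
#' @export
setGeneric("pseudotime", function(x) standardGeneric("pseudotime"))

#' @rdname CellOrdering-accessors
#' @export
setGeneric("branchIds", function(x) standardGeneric("branchIds"))

#' @rdname TransitionGraph-accessors
#' @export
setGeneric("stationaryProbs", function(x) standardGeneric("stationaryProbs"))

#' @rdname TransitionGraph-accessors
#' @export
setGeneric("conditionalProbs", function(x) standardGeneric("conditionalProbs"))

#' @rdname CellTypeDynamics-accessors
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))

#' @rdname CellTypeDynamics-accessors
#' @export
setGeneric("fateProbs", function(x) standardGeneric("fateProbs"))

#' @rdname CellTypeDynamics-accessors
#' @export
setGeneric("exitProbs", function(x) standardGeneric("exitProbs"))

#' @rdname CellTypeAssignment-accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname CellTypeAssignment-accessors
#' @export
setGeneric("cellSubtypes", function(x) standardGeneric("cellSubtypes"))
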