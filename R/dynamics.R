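#' Assign branch-level cell types
#'
#' Each maximal unbranched edge chain of the backbone is one cell type, so
#' the number of types equals the number of branches. The chains were
#' enumerated deterministically during projection (root-first, children in
#' ascending node id); each cell inherits the chain of its projection.
#'
#' @param ordering a [CellOrdering-class].
#' @return a [CellTypeAssignment-class] with subtypes unset.
#' @export
assignCellTypes <- function(ordering) {
  nTypes <- max(ordering@chainOfEdge, 1L)
  typeId <- ordering@branchId
  typeId[is.na(typeId) | typeId == 0L] <- 1L
  new("CellTypeAssignment", typeId = as.integer(typeId),
      subtypeId = rep(NA_integer_, length(typeId)),
      nTypes = as.integer(nTypes))
}

#' Detect potential-well subtypes along each branch
#'
#' Within each branch, the per-cell landscape potential is smoothed
#' against pseudotime with a moving-average window (default 5% of the
#' branch's pseudotime range). Local minima of the smoothed profile that
#' are separated by barriers of at least `barrierMin` (in natural-log
#' units, measured from the higher of the two flanking minima to the
#' intervening maximum) define the wells; each cell joins the well whose
#' basin — delimited by the maxima flanking the minimum — contains its
#' pseudotime. Every well is one cell subtype.
#'
#' @param assignment a [CellTypeAssignment-class].
#' @param potentials per-cell potentials from [cellPotentials()].
#' @param ordering the [CellOrdering-class].
#' @param window moving-average window as a fraction of the branch's
#'   pseudotime range (default 0.05).
#' @param barrierMin minimum barrier height retaining a well split
#'   (default 0.1; `Inf` forces one subtype per branch).
#' @return the assignment with `subtypeId` filled (numbered within each
#'   branch).
#' @export
detectSubtypeWells <- function(assignment, potentials, ordering,
                               window = 0.05, barrierMin = 0.1) {
  .checkScalar(window, "window", 0, 1, openLo = TRUE)
  typeId <- assignment@typeId
  tau <- ordering@pseudotime
  subtype <- rep(NA_integer_, length(typeId))
  for (ty in sort(unique(typeId))) {
    cells <- which(typeId == ty)
    if (length(cells) < 10L) {
      warning("branch ", ty, " has fewer than 10 cells: single subtype")
      subtype[cells] <- 1L
      next
    }
    o <- cells[order(tau[cells])]
    tt <- tau[o]
    ee <- potentials[o]
    span <- diff(range(tt))
    if (span == 0) { subtype[cells] <- 1L; next }
    w <- window * span
    smoothed <- vapply(seq_along(tt), function(i)
      mean(ee[abs(tt - tt[i]) <= w / 2]), numeric(1L))
    minima <- .localMinima(smoothed)
    # merge minima split by barriers shallower than barrierMin
    while (length(minima) > 1L) {
      depths <- vapply(seq_len(length(minima) - 1L), function(i) {
        seg <- smoothed[minima[i]:minima[i + 1L]]
        max(seg) - max(smoothed[minima[i]], smoothed[minima[i + 1L]])
      }, numeric(1L))
      if (all(depths >= barrierMin)) break
      i <- which.min(depths)
      drop <- if (smoothed[minima[i]] >= smoothed[minima[i + 1L]])
        i else i + 1L
      minima <- minima[-drop]
    }
    if (length(minima) <= 1L) {
      subtype[cells] <- 1L
      next
    }
    # basin boundaries at the maxima between consecutive surviving minima
    bounds <- vapply(seq_len(length(minima) - 1L), function(i) {
      seg <- minima[i]:minima[i + 1L]
      seg[which.max(smoothed[seg])]
    }, integer(1L))
    wellOfPos <- findInterval(seq_along(smoothed),
                              c(1L, bounds + 1L))
    subtype[o] <- wellOfPos
  }
  assignment@subtypeId <- subtype
  assignment
}

.localMinima <- function(x) {
  n <- length(x)
  if (n < 3L) return(if (n) which.min(x) else integer(0))
  mins <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L  # plateau
    leftUp <- i == 1L || x[i - 1L] > x[i]
    rightUp <- j == n || x[j + 1L] > x[i]
    if (leftUp && rightUp) mins <- c(mins, i)
    i <- j + 1L
  }
  mins
}

#' Stationary visit rate on every directed link
#'
#' q(alpha -> beta) = p_alpha * p(alpha -> beta): the long-run rate at
#' which the walker traverses the link. Summed over all links this is
#' exactly 1.
#'
#' @param graph a [TransitionGraph-class] with a converged stationary
#'   distribution.
#' @return data.frame with columns `from`, `to`, `q`.
#' @export
linkVisitRates <- function(graph) {
  p <- stationaryProbs(graph)
  if (!length(graph@conditional))
    stop("call conditionalProbabilities() first")
  data.frame(from = graph@from, to = graph@to,
             q = p[graph@from] * graph@conditional)
}

#' Cell-type transition, exit, and fate probabilities
#'
#' Aggregates the link visit rates over the type partition:
#' q(i -> j) sums the rates of links from cells of type i into cells of
#' type j (for j != i), the exit probability of type i sums all links
#' leaving i, and fate_i = 1 - exit_i. By construction
#' exit_i = sum over j != i of q(i -> j), and a type with no outgoing
#' links has fate 1.
#'
#' Setting `printedIndexSet = TRUE` switches q(i -> j) to summing links
#' from i into *everything except* j — an alternative (internally
#' inconsistent) reading kept for comparison only.
#'
#' @param rates link rates from [linkVisitRates()].
#' @param assignment a [CellTypeAssignment-class].
#' @param printedIndexSet debug flag, see above (default FALSE).
#' @return a [CellTypeDynamics-class].
#' @export
cellTypeDynamics <- function(rates, assignment, printedIndexSet = FALSE) {
  typeId <- assignment@typeId
  k <- assignment@nTypes
  ti <- typeId[rates$from]
  tj <- typeId[rates$to]
  flux <- matrix(0, k, k)
  agg <- rowsum(rates$q, interaction(factor(ti, levels = seq_len(k)),
                                     factor(tj, levels = seq_len(k)),
                                     drop = FALSE))
  idx <- strsplit(rownames(agg), ".", fixed = TRUE)
  for (r in seq_along(idx))
    flux[as.integer(idx[[r]][1L]), as.integer(idx[[r]][2L])] <-
      agg[r, 1L]
  internal <- diag(flux)
  qExit <- rowSums(flux) - internal
  qMat <- flux
  diag(qMat) <- 0
  if (printedIndexSet) {
    # q(i -> j) = flux from i to everything but j, as printed
    outTotal <- rowSums(flux)
    qMat <- matrix(outTotal, k, k) - flux
    diag(qMat) <- 0
  }
  new("CellTypeDynamics", qMatrix = qMat, qExit = as.numeric(qExit),
      fate = 1 - as.numeric(qExit), internalFlux = as.numeric(internal))
}
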