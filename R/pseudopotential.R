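#' Compute the per-cell pseudo-potential field
#'
#' The local density of a cell x is the Gaussian-kernel sum
#' rho(x) = sum over all cells y (including y = x) of
#' exp(-d(x, y)^2 / (2 sigma^2)); the pseudo-potential is
#' Etilde(x) = -log rho(x). Dense regions have low pseudo-potential;
#' valley floors of this field trace the trajectory backbone.
#'
#' @param cs a [CellStateSet-class].
#' @param context a [DistanceContext-class] with positive sigma
#'   (see [deriveSigma()]).
#' @return a [PseudoPotentialField-class].
#' @export
computePseudoPotential <- function(cs, context) {
  stopifnot(is(context, "DistanceContext"))
  if (is.na(context@sigma) || context@sigma <= 0)
    stop("context must carry a positive sigma")
  coords <- stateCoords(cs)
  d2 <- as.matrix(dist(coords))^2
  if (any(!is.finite(d2))) stop("non-finite cell-cell distance")
  rho <- rowSums(exp(-d2 / (2 * context@sigma^2)))
  names(rho) <- cellIds(cs)
  new("PseudoPotentialField", rho = rho, eTilde = -log(rho),
      context = context)
}

#' Decision-graph distance delta within a subset of cells
#'
#' For each cell in `subset`, delta is the distance to the nearest cell of
#' the subset with strictly lower pseudo-potential; for the subset's
#' minimum-pseudo-potential cell it is the maximum distance to any other
#' subset member. Ties in the pseudo-potential are broken by cell index
#' (the lower index is treated as lower). Together with the
#' pseudo-potential this is the decision-graph statistic used to find
#' well centers (density peaks) on super-rings.
#'
#' @param subset integer cell indices (non-empty).
#' @param field a [PseudoPotentialField-class] over all cells.
#' @param cs the [CellStateSet-class] the field was computed on.
#' @return numeric delta values aligned with `subset`.
#' @export
computeDelta <- function(subset, field, cs) {
  subset <- as.integer(subset)
  if (!length(subset)) stop("'subset' must be non-empty")
  if (length(subset) == 1L) {
    warning("singleton subset: delta = 0 by convention")
    return(0)
  }
  coords <- stateCoords(cs)[subset, , drop = FALSE]
  e <- field@eTilde[subset]
  k <- length(subset)
  d <- as.matrix(dist(coords))
  # rank by (pseudo-potential, cell index): lower index wins ties
  ord <- order(e, subset)
  rank <- integer(k); rank[ord] <- seq_len(k)
  delta <- numeric(k)
  for (i in seq_len(k)) {
    lower <- rank < rank[i]
    delta[i] <- if (!any(lower)) max(d[i, -i]) else min(d[i, lower])
  }
  delta
}
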