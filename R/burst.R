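#' Gamma maximum-likelihood fit of bursting parameters
#'
#' Models the nonzero expression values of one gene in one pseudotime
#' window as draws from a Gamma distribution with shape `a` (mean burst
#' frequency: bursts per cell cycle) and scale `b` (mean burst size:
#' transcripts per burst). The MLE solves
#' log(a) - digamma(a) = log(mean(x)) - mean(log(x))
#' by safeguarded Newton iteration started from the method-of-moments
#' value a0 = mean^2 / var, with b = mean(x) / a. Every converged fit
#' satisfies the first-moment identity a * b = mean(x).
#'
#' @param observations positive values (the window's nonzero expression
#'   of one gene); zeros/negatives are rejected.
#' @param minObs minimum sample size (default 20).
#' @param tol convergence tolerance on successive shape iterates
#'   (default 1e-10).
#' @param maxIter Newton iteration cap (default 200).
#' @return list with `a`, `b`, `nUsed`, `converged`, `degenerate`,
#'   `loglik` (`a`/`b` are NA when not estimable).
#' @export
fitGammaMLE <- function(observations, minObs = 20L, tol = 1e-10,
                        maxIter = 200L) {
  x <- as.numeric(observations)
  if (any(x <= 0)) stop("observations must be strictly positive ",
                        "(drop zeros before fitting)")
  n <- length(x)
  out <- list(a = NA_real_, b = NA_real_, nUsed = n, converged = FALSE,
              degenerate = FALSE, loglik = NA_real_)
  if (n < minObs) return(out)
  xbar <- mean(x)
  s <- log(xbar) - mean(log(x))  # >= 0 by Jensen; 0 iff all equal
  if (var(x) == 0 || s <= .Machine$double.eps) {
    out$degenerate <- TRUE  # a -> Inf limit: no burst-size dispersion
    return(out)
  }
  a <- xbar^2 / var(x)  # method-of-moments start
  if (!is.finite(a) || a <= 0) a <- 0.5 / s
  lo <- 0; hi <- Inf  # safeguarding bracket: f is decreasing in a
  f <- function(a) log(a) - digamma(a) - s
  for (it in seq_len(maxIter)) {
    fa <- f(a)
    if (fa > 0) lo <- a else hi <- a
    step <- fa / (1 / a - trigamma(a))
    aNew <- a - step
    if (!is.finite(aNew) || aNew <= lo || aNew >= hi)
      aNew <- if (is.finite(hi)) (lo + hi) / 2 else a * 2
    if (abs(aNew - a) < tol * max(1, a)) {
      a <- aNew
      out$converged <- TRUE
      break
    }
    a <- aNew
  }
  if (!out$converged) return(out)
  b <- xbar / a
  out$a <- a
  out$b <- b
  out$loglik <- sum((a - 1) * log(x) - x / b - a * log(b) - lgamma(a))
  out
}

#' Classify a fitted gene into a bursting quadrant
#'
#' High frequency means shape a above `bfThreshold` (default 0.33 bursts
#' per cell cycle); small burst means scale b below `bsThreshold`
#' (default 200 transcripts). A gene is called bursty unless it falls in
#' the high-frequency/small-burst quadrant. With `mode =
#' "dataset-mean"`, the thresholds are instead the means of the supplied
#' fitted values (`allA`, `allB`).
#'
#' @param a,b fitted shape and scale (converged fit required).
#' @param bfThreshold,bsThreshold fixed thresholds (defaults 0.33, 200).
#' @param mode `"fixed"` or `"dataset-mean"`.
#' @param allA,allB all converged fits of the window, for
#'   `"dataset-mean"`.
#' @return list with `quadrant` (one of "high-freq small-burst",
#'   "high-freq large-burst", "low-freq small-burst", "low-freq
#'   large-burst") and `bursty` (flag).
#' @export
classifyBurstQuadrant <- function(a, b, bfThreshold = 0.33,
                                  bsThreshold = 200,
                                  mode = c("fixed", "dataset-mean"),
                                  allA = NULL, allB = NULL) {
  mode <- match.arg(mode)
  if (is.na(a) || is.na(b))
    return(list(quadrant = NA_character_, bursty = NA))
  if (mode == "dataset-mean") {
    if (is.null(allA) || is.null(allB))
      stop("mode = 'dataset-mean' needs allA and allB")
    bfThreshold <- mean(allA, na.rm = TRUE)
    bsThreshold <- mean(allB, na.rm = TRUE)
  }
  hf <- a > bfThreshold
  sb <- b < bsThreshold
  quadrant <- paste0(if (hf) "high-freq" else "low-freq", " ",
                     if (sb) "small-burst" else "large-burst")
  list(quadrant = quadrant, bursty = !(hf && sb))
}

#' Bursting-kinetics trajectories along pseudotime
#'
#' Fits the Gamma bursting model per gene per window and summarizes each
#' window by the mean fitted burst frequency and size over converged
#' fits, the mean expression level (zeros included), and the fraction of
#' converged genes classified as bursty. Branch scopes are carried
#' through so pre- and post-branch trends stay separable.
#'
#' @param cs the [CellStateSet-class].
#' @param ordering the [CellOrdering-class].
#' @param windows list from [makePseudotimeWindows()].
#' @param genes gene ids to fit (default: all).
#' @param minObs minimum nonzero observations per fit (default 20).
#' @param bfThreshold,bsThreshold quadrant thresholds (defaults 0.33,
#'   200).
#' @param thresholdMode `"fixed"` or `"dataset-mean"` (see
#'   [classifyBurstQuadrant()]).
#' @return list with `fits` (one row per gene per window) and `summary`
#'   (one row per window; windows with no converged fit keep NA means as
#'   a gap record).
#' @export
burstTrajectories <- function(cs, ordering, windows, genes = NULL,
                              minObs = 20L, bfThreshold = 0.33,
                              bsThreshold = 200,
                              thresholdMode = c("fixed",
                                                "dataset-mean")) {
  thresholdMode <- match.arg(thresholdMode)
  if (is.null(genes)) genes <- geneIds(cs)
  v <- exprValues(cs)[, genes, drop = FALSE]
  fitRows <- list()
  sumRows <- list()
  for (wi in seq_along(windows)) {
    w <- windows[[wi]]
    sub <- v[w$cells, , drop = FALSE]
    fits <- lapply(genes, function(g) {
      xs <- sub[, g]
      xs <- xs[xs > 0]
      f <- if (length(xs)) fitGammaMLE(xs, minObs = minObs) else
        list(a = NA_real_, b = NA_real_, nUsed = 0L, converged = FALSE,
             degenerate = FALSE, loglik = NA_real_)
      data.frame(gene = g, window = wi, center = w$center,
                 scope = w$scope, a = f$a, b = f$b, n_used = f$nUsed,
                 converged = f$converged, loglik = f$loglik)
    })
    fits <- do.call(rbind, fits)
    conv <- fits[fits$converged, , drop = FALSE]
    if (nrow(conv)) {
      cls <- mapply(function(a, b)
        classifyBurstQuadrant(a, b, bfThreshold, bsThreshold,
                              mode = thresholdMode,
                              allA = conv$a, allB = conv$b)$bursty,
        conv$a, conv$b)
      burstyFraction <- mean(cls)
      fits$bursty <- NA
      fits$bursty[fits$converged] <- cls
    } else burstyFraction <- NA_real_
    sumRows[[wi]] <- data.frame(
      window = wi, center = w$center, scope = w$scope,
      mean_a = if (nrow(conv)) mean(conv$a) else NA_real_,
      mean_b = if (nrow(conv)) mean(conv$b) else NA_real_,
      mean_expression = mean(sub),
      bursty_fraction = burstyFraction,
      n_converged = nrow(conv), n_cells = length(w$cells))
    fitRows[[wi]] <- fits
  }
  list(fits = do.call(rbind, fitRows),
       summary = do.call(rbind, sumRows))
}
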