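# Seeded synthetic-data generators with machine-readable ground truth.
# The latent skeletons below (trunk lengths, branch angles) are fixed
# design choices: arms diverge widely enough that wells one ring apart
# stay separated, and every topology fits in a unit-free latent plane.

.topologySegments <- function(topology) {
  deg2rad <- function(d) d * pi / 180
  seg <- function(x0, y0, ang, len, t0, t1, branch, parent) {
    list(a = c(x0, y0),
         b = c(x0 + len * cos(ang), y0 + len * sin(ang)),
         t0 = t0, t1 = t1, branch = branch, parent = parent, ang = ang)
  }
  switch(topology,
    linear = list(
      segments = list(seg(0, 0, 0, 10, 0, 1, 0L, NA)),
      branchPoints = numeric(0)),
    bifurcation = {
      s0 <- seg(0, 0, 0, 5, 0, 0.5, 0L, NA)
      list(segments = list(
        s0,
        seg(5, 0, deg2rad(45), 5, 0.5, 1, 1L, 0L),
        seg(5, 0, deg2rad(-45), 5, 0.5, 1, 2L, 0L)),
        branchPoints = 0.5)
    },
    `double-bifurcation` = {
      a1 <- deg2rad(50); a2 <- deg2rad(-50)
      up <- c(4 + 3 * cos(a1), 3 * sin(a1))
      list(segments = list(
        seg(0, 0, 0, 4, 0, 0.4, 0L, NA),
        seg(4, 0, a1, 3, 0.4, 0.7, 1L, 0L),
        seg(4, 0, a2, 6, 0.4, 1, 2L, 0L),
        seg(up[1], up[2], a1 + deg2rad(45), 3, 0.7, 1, 3L, 1L),
        seg(up[1], up[2], a1 - deg2rad(45), 3, 0.7, 1, 4L, 1L)),
        branchPoints = c(0.4, 0.7))
    },
    trifurcation = {
      list(segments = list(
        seg(0, 0, 0, 5, 0, 0.5, 0L, NA),
        seg(5, 0, deg2rad(70), 5, 0.5, 1, 1L, 0L),
        seg(5, 0, 0, 5, 0.5, 1, 2L, 0L),
        seg(5, 0, deg2rad(-70), 5, 0.5, 1, 3L, 0L)),
        branchPoints = 0.5)
    },
    stop("unknown topology '", topology, "'"))
}

# Latent position of one cell given its time and chosen leaf-branch path.
.latentPosition <- function(t, segs, branchChoice) {
  # find the segment chain: walk segments whose [t0, t1] contains t,
  # consistent with the chosen terminal branch
  path <- segs$segments[[branchChoice$segIdx]]
  frac <- (t - path$t0) / (path$t1 - path$t0)
  path$a + (path$b - path$a) * frac
}

#' Simulate cells on a noisy branched trajectory
#'
#' Cells are placed on a piecewise-linear latent skeleton in a 2-D plane
#' (linear path, single bifurcation, double bifurcation, or
#' trifurcation), embedded into gene space by a seeded random orthonormal
#' linear map with per-gene positive offsets (so expression stays
#' nonnegative), and perturbed by isotropic Gaussian noise. Latent times
#' are uniform by default; the `"early-dense"` profile concentrates cells
#' at early times (Beta(1, 2)), the configuration used to contrast
#' pseudo-potential with landscape potential.
#'
#' @param nCells number of cells (>= 100, the backbone minimum).
#' @param topology one of `"linear"`, `"bifurcation"`,
#'   `"double-bifurcation"`, `"trifurcation"`.
#' @param nGenes number of genes (>= 2; default 50).
#' @param noiseSd isotropic Gaussian noise sd per gene (default 0.05).
#' @param densityProfile `"uniform"` or `"early-dense"`.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return list with `cs` (a [CellStateSet-class]) and `truth`
#'   (list: `cells` data.frame with `cell_id`, `t`, `branch`;
#'   `branchPoints`; `topology`; `latent` coordinates).
#' @export
simulateBranchingTrajectory <- function(nCells = 1000L,
                                        topology = c("linear",
                                                     "bifurcation",
                                                     "double-bifurcation",
                                                     "trifurcation"),
                                        nGenes = 50L, noiseSd = 0.05,
                                        densityProfile = c("uniform",
                                                           "early-dense"),
                                        seed = 1L) {
  topology <- match.arg(topology)
  densityProfile <- match.arg(densityProfile)
  nCells <- as.integer(nCells); nGenes <- as.integer(nGenes)
  .checkScalar(nCells, "nCells", 100, Inf)
  .checkScalar(nGenes, "nGenes", 2, Inf)
  .checkScalar(noiseSd, "noiseSd", 0, Inf)
  set.seed(as.integer(seed))
  segs <- .topologySegments(topology)
  t <- switch(densityProfile,
              uniform = runif(nCells),
              `early-dense` = stats::rbeta(nCells, 1, 2))
  # assign branches: cells pick a segment whose time range contains t;
  # among simultaneous arms the choice is uniform
  segIdx <- integer(nCells)
  branch <- integer(nCells)
  for (i in seq_len(nCells)) {
    containing <- which(vapply(segs$segments, function(s)
      t[i] >= s$t0 && t[i] <= s$t1, logical(1L)))
    # when a segment and one of its children both contain t (the branch
    # instant), the children win
    parents <- vapply(segs$segments[containing], function(s)
      if (is.na(s$parent)) NA_integer_ else s$parent, integer(1L))
    branches <- vapply(segs$segments[containing], function(s) s$branch,
                       integer(1L))
    containing <- containing[!(branches %in% parents)]
    pick <- containing[sample.int(length(containing), 1L)]
    segIdx[i] <- pick
    branch[i] <- segs$segments[[pick]]$branch
  }
  latent <- t(vapply(seq_len(nCells), function(i)
    .latentPosition(t[i], segs, list(segIdx = segIdx[i])),
    numeric(2L)))
  # seeded random orthonormal embedding, then positive per-gene offsets
  basis <- qr.Q(qr(matrix(rnorm(nGenes * 2L), nGenes, 2L)))
  offsets <- runif(nGenes, 6, 10)
  values <- latent %*% t(basis)
  values <- sweep(values, 2L, offsets, "+")
  if (noiseSd > 0)
    values <- values + matrix(rnorm(nCells * nGenes, sd = noiseSd),
                              nCells, nGenes)
  values <- pmax(values, 0)
  dimnames(values) <- list(sprintf("cell%04d", seq_len(nCells)),
                           sprintf("gene%03d", seq_len(nGenes)))
  cellsDf <- data.frame(cell_id = rownames(values), t = t,
                        branch = branch)
  list(cs = CellStateSet(values),
       truth = list(cells = cellsDf, branchPoints = segs$branchPoints,
                    topology = topology, latent = latent))
}

#' Simulate Gamma-bursty expression along pseudotime
#'
#' Each gene's expression in each cell is a Gamma draw with shape a(tau)
#' (mean burst frequency) and scale b(tau) (mean burst size) evaluated at
#' the cell's pseudotime, optionally zeroed with probability
#' `dropoutRate` (technical dropout). The per-gene non-dropout sample
#' mean converges to a * b.
#'
#' @param nCells number of cells.
#' @param geneParams list of per-gene parameter pairs; each element is a
#'   list with `a` and `b`, each either a positive constant or a function
#'   of tau returning positive values.
#' @param tau per-cell pseudotimes in `[0, 1]`.
#' @param dropoutRate probability of zeroing an entry (in `[0, 1)`).
#' @param seed integer seed.
#' @return list with `cs` (a [CellStateSet-class]) and `truth` (the
#'   evaluated per-cell a and b matrices).
#' @export
simulateBurstyExpression <- function(nCells, geneParams, tau,
                                     dropoutRate = 0, seed = 1L) {
  nCells <- as.integer(nCells)
  .checkScalar(dropoutRate, "dropoutRate", 0, 1, openHi = TRUE)
  if (length(tau) != nCells) stop("need one tau per cell")
  set.seed(as.integer(seed))
  nG <- length(geneParams)
  evalParam <- function(p) {
    v <- if (is.function(p)) p(tau) else rep(p, nCells)
    if (any(!is.finite(v) | v <= 0))
      stop("gene parameters must be positive everywhere")
    v
  }
  aMat <- vapply(geneParams, function(g) evalParam(g$a),
                 numeric(nCells))
  bMat <- vapply(geneParams, function(g) evalParam(g$b),
                 numeric(nCells))
  values <- matrix(rgamma(nCells * nG, shape = aMat, scale = bMat),
                   nCells, nG)
  if (dropoutRate > 0) {
    drop <- matrix(runif(nCells * nG) < dropoutRate, nCells, nG)
    values[drop] <- 0
  }
  dimnames(values) <- list(sprintf("cell%04d", seq_len(nCells)),
                           sprintf("gene%03d", seq_len(nG)))
  list(cs = CellStateSet(values),
       truth = list(a = aMat, b = bMat, dropoutRate = dropoutRate))
}

#' Simulate a regulator-target gene panel with tunable coupling
#'
#' Regulator genes are i.i.d. standard normal across cells; each target
#' equals the sum of coefficient * couplingProfile(tau) * regulator over
#' its wiring entries plus Gaussian noise whose sd may also depend on
#' tau; decoy genes are independent noise. All genes receive a fixed
#' per-gene baseline offset (drawn once, N(8, 1)) so cell-cell
#' correlations across genes are defined, and values are clamped at zero
#' to remain valid expression levels. Wiring must be acyclic (targets are
#' generated in topological order).
#'
#' @param nCells number of cells.
#' @param wiring data.frame with columns `regulator`, `target`,
#'   `coefficient` (character gene ids).
#' @param couplingProfile function of tau scaling every coefficient
#'   (default: constant 1).
#' @param noiseSd target noise sd: a constant or a function of tau
#'   (default 0.1).
#' @param nDecoys number of independent decoy genes (default 0).
#' @param tau per-cell pseudotimes (default: uniform grid on `[0, 1]`).
#' @param seed integer seed.
#' @return list with `cs` (a [CellStateSet-class]), `tau`, and `truth`
#'   (the wiring).
#' @export
simulateRegulatoryPanel <- function(nCells, wiring,
                                    couplingProfile = function(tau) 1,
                                    noiseSd = 0.1, nDecoys = 0L,
                                    tau = NULL, seed = 1L) {
  nCells <- as.integer(nCells)
  set.seed(as.integer(seed))
  if (is.null(tau)) tau <- seq(0, 1, length.out = nCells)
  if (length(tau) != nCells) stop("need one tau per cell")
  regs <- unique(wiring$regulator)
  targets <- unique(wiring$target)
  # topological order; fails on cycles
  order <- character(0)
  pending <- targets
  known <- setdiff(regs, targets)
  while (length(pending)) {
    ready <- pending[vapply(pending, function(tg) {
      needs <- wiring$regulator[wiring$target == tg]
      all(needs %in% c(known, order))
    }, logical(1L))]
    if (!length(ready)) stop("cyclic wiring")
    order <- c(order, ready)
    pending <- setdiff(pending, ready)
  }
  coupling <- couplingProfile(tau)
  if (length(coupling) == 1L) coupling <- rep(coupling, nCells)
  sdVec <- if (is.function(noiseSd)) noiseSd(tau) else
    rep(noiseSd, nCells)
  genes <- c(setdiff(regs, targets), order,
             if (nDecoys > 0) sprintf("decoy%02d", seq_len(nDecoys)))
  values <- matrix(0, nCells, length(genes),
                   dimnames = list(sprintf("cell%04d", seq_len(nCells)),
                                   genes))
  for (g in setdiff(regs, targets))
    values[, g] <- rnorm(nCells)
  for (g in order) {
    wi <- wiring[wiring$target == g, , drop = FALSE]
    signal <- rep(0, nCells)
    for (r in seq_len(nrow(wi)))
      signal <- signal +
        wi$coefficient[r] * coupling * values[, wi$regulator[r]]
    values[, g] <- signal + rnorm(nCells, sd = sdVec)
  }
  if (nDecoys > 0)
    for (g in sprintf("decoy%02d", seq_len(nDecoys)))
      values[, g] <- rnorm(nCells)
  baseline <- rnorm(length(genes), mean = 8, sd = 1)
  values <- sweep(values, 2L, baseline, "+")
  values <- pmax(values, 0)
  list(cs = CellStateSet(values), tau = tau,
       truth = list(wiring = wiring))
}
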