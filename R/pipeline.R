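#' Default run configuration for the full pipeline
#'
#' One flat, human-editable list of every tunable, namespaced by module.
#' Values can be overridden by a JSON config file and by per-call
#' overrides; the effective configuration is serialized into the run
#' manifest. Defaults: sigma quantile 0.02, ring base radius 3 sigma,
#' annulus half-width sigma, at least 10 ring cells, chi = 30,
#' epsilon = 0.01, 10 nearest neighbors, 10 half-overlapping windows.
#'
#' @param ... name = value overrides of any default.
#' @return named list of class `runConfig`.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    # simulate
    simulate.nCells = 1000L, simulate.topology = "bifurcation",
    simulate.nGenes = 50L, simulate.noiseSd = 0.05,
    simulate.densityProfile = "uniform",
    # io / preprocess
    io.minExpressingFraction = 0.05, io.logTransform = FALSE,
    io.reduceTo = NA_integer_, io.sigmaQuantile = 0.02,
    # backbone
    backbone.baseRadiusFactor = 3, backbone.halfWidthFactor = 1,
    backbone.minRingCells = 10L, backbone.radiusGrowth = 1.1,
    backbone.deltaMinFactor = 0.5, backbone.excludeFactor = 1,
    backbone.mergeFactor = 1, backbone.maxDepth = 50L,
    backbone.minCellsTotal = 100L, backbone.nSubdivisions = 0L,
    # landscape
    landscape.chi = 30, landscape.kNeighbors = 10L, landscape.W0 = 1,
    landscape.epsilon = 0.01, landscape.tol = 1e-10,
    landscape.maxIter = 10000L, landscape.teleport = "out-weight",
    landscape.gridResolution = 200L, landscape.smoothingBandwidth = 2,
    # dynamics
    dynamics.subtypeWindow = 0.05, dynamics.barrierMin = 0.1,
    # network
    network.nWindows = 10L, network.overlapFraction = 0.5,
    network.perBranch = TRUE, network.minCellsPerWindow = 30L,
    network.panelSize = 10L, network.nTrees = 500L,
    network.kPartners = 6L, network.mutualThreshold = 0.3,
    network.ratioFloor = 0.05, network.coreGene = NA_character_,
    # burst
    burst.minObs = 20L, burst.bfThreshold = 0.33,
    burst.bsThreshold = 200, burst.thresholdMode = "fixed")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "runConfig")
}

.validateConfig <- function(cfg) {
  .checkScalar(cfg$io.sigmaQuantile, "io.sigmaQuantile", 0, 1,
               openLo = TRUE, openHi = TRUE)
  .checkScalar(cfg$landscape.chi, "landscape.chi", 0, Inf,
               openLo = TRUE)
  .checkScalar(cfg$landscape.epsilon, "landscape.epsilon", 0, 1,
               openLo = TRUE, openHi = TRUE)
  .checkScalar(cfg$network.overlapFraction, "network.overlapFraction",
               0, 1, openHi = TRUE)
  .checkScalar(cfg$burst.bfThreshold, "burst.bfThreshold", 0, Inf)
  .checkScalar(cfg$burst.bsThreshold, "burst.bsThreshold", 0, Inf)
  invisible(cfg)
}

.artifact <- function(runDir, name) file.path(runDir, name)

.needArtifact <- function(runDir, name, producer) {
  p <- .artifact(runDir, name)
  if (!file.exists(p))
    stop("missing upstream artifact '", name, "' in ", runDir,
         ": run the '", producer, "' stage first")
  p
}

.writeManifest <- function(runDir, cfg, stages) {
  manifest <- list(
    package = "scLandscape",
    version = as.character(utils::packageVersion("scLandscape")),
    stages = stages,
    config = unclass(cfg))
  jsonlite::write_json(manifest, .artifact(runDir, "run-manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run one pipeline stage (or all of them)
#'
#' Orchestrates the pipeline over plain-text artifacts in a run
#' directory: `simulate` writes `matrix.csv` and ground truth;
#' `backbone` pre-processes the matrix, grows and refines the backbone
#' and writes the ordering and tree; `landscape` solves the random walk
#' and writes per-cell potentials plus the surface grid; `dynamics`
#' writes type assignments and fate/transition probabilities; `network`
#' writes the correlation-degree trajectory and per-window importance
#' matrices; `burst` writes per-gene fits and window summaries. `all`
#' chains every stage. Each stage records itself in the deterministic
#' JSON run manifest; stages never mutate upstream artifacts, so
#' re-running with identical config and seed is idempotent.
#'
#' @param stage one of `"simulate"`, `"backbone"`, `"landscape"`,
#'   `"dynamics"`, `"network"`, `"burst"`, `"all"`.
#' @param config a [defaultRunConfig()] list.
#' @param runDir run directory (created if missing).
#' @param matrixFile optional external input matrix for `backbone`
#'   (defaults to the simulated `matrix.csv` in `runDir`).
#' @return invisibly, a character vector of artifact paths written.
#' @export
runStage <- function(stage = c("all", "simulate", "backbone",
                               "landscape", "dynamics", "network",
                               "burst"),
                     config = defaultRunConfig(), runDir,
                     matrixFile = NULL) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "runConfig"))
  .validateConfig(config)
  dir.create(runDir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    paths <- character(0)
    for (s in c("simulate", "backbone", "landscape", "dynamics",
                "network", "burst"))
      paths <- c(paths, runStage(s, config, runDir,
                                 matrixFile = matrixFile))
    return(invisible(paths))
  }
  cfg <- config
  written <- character(0)
  logLine <- function(...) {
    cat(format(Sys.time(), "%H:%M:%OS2"), stage, "-", ..., "\n",
        file = .artifact(runDir, "run.log"), append = TRUE)
  }

  if (stage == "simulate") {
    sim <- simulateBranchingTrajectory(
      nCells = cfg$simulate.nCells, topology = cfg$simulate.topology,
      nGenes = cfg$simulate.nGenes, noiseSd = cfg$simulate.noiseSd,
      densityProfile = cfg$simulate.densityProfile, seed = cfg$seed)
    writeExpressionMatrix(sim$cs, .artifact(runDir, "matrix.csv"))
    utils::write.csv(sim$truth$cells,
                     .artifact(runDir, "truth-cells.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(topology = sim$truth$topology,
           branch_points = sim$truth$branchPoints),
      .artifact(runDir, "truth-meta.json"), auto_unbox = TRUE,
      digits = NA)
    written <- c(written, "matrix.csv", "truth-cells.csv",
                 "truth-meta.json")
    logLine("simulated", cfg$simulate.nCells, "cells,",
            cfg$simulate.topology)
  }

  if (stage == "backbone") {
    input <- if (!is.null(matrixFile)) matrixFile else
      .needArtifact(runDir, "matrix.csv", "simulate")
    cs <- readExpressionMatrix(input)
    cs <- preprocessCells(cs,
      minExpressingFraction = cfg$io.minExpressingFraction,
      logTransform = cfg$io.logTransform,
      reduceTo = if (is.na(cfg$io.reduceTo)) NULL else cfg$io.reduceTo)
    writeExpressionMatrix(cs, .artifact(runDir, "preprocessed.csv"))
    ctx <- deriveSigma(cs, cfg$io.sigmaQuantile)
    field <- computePseudoPotential(cs, ctx)
    params <- backboneParams(
      baseRadiusFactor = cfg$backbone.baseRadiusFactor,
      halfWidthFactor = cfg$backbone.halfWidthFactor,
      minRingCells = cfg$backbone.minRingCells,
      radiusGrowth = cfg$backbone.radiusGrowth,
      deltaMinFactor = cfg$backbone.deltaMinFactor,
      excludeFactor = cfg$backbone.excludeFactor,
      mergeFactor = cfg$backbone.mergeFactor,
      maxDepth = cfg$backbone.maxDepth,
      minCellsTotal = cfg$backbone.minCellsTotal)
    tree <- growBackboneTree(cs, field, params = params)
    if (cfg$backbone.nSubdivisions > 0L)
      tree <- refineBackboneTree(tree, field, cs,
                                 nSubdivisions =
                                   cfg$backbone.nSubdivisions)
    ordering <- projectCells(tree, cs)
    utils::write.csv(as.data.frame(ordering),
                     .artifact(runDir, "ordering.csv"),
                     row.names = FALSE)
    nodeTab <- data.frame(node = seq_along(tree@nodeCells),
                          cell_id = cellIds(cs)[tree@nodeCells])
    red <- tree@nodeCoords
    colnames(red) <- paste0("reduced_", seq_len(ncol(red)))
    orig <- exprValues(cs)[tree@nodeCells, , drop = FALSE]
    utils::write.csv(cbind(nodeTab, red, orig),
                     .artifact(runDir, "tree-nodes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(nodes = tree@nodeCells,
           edges = apply(tree@edges, 1L, as.list),
           root = ordering@rootNode,
           sigma = ctx@sigma),
      .artifact(runDir, "tree.json"), auto_unbox = TRUE, digits = NA)
    written <- c(written, "preprocessed.csv", "ordering.csv",
                 "tree-nodes.csv", "tree.json")
    logLine("backbone with", length(tree@nodeCells), "nodes")
  }

  if (stage %in% c("landscape", "dynamics", "network", "burst")) {
    ordPath <- .needArtifact(runDir, "ordering.csv", "backbone")
    prePath <- .needArtifact(runDir, "preprocessed.csv", "backbone")
    cs <- readExpressionMatrix(prePath)
    if (!is.na(cfg$io.reduceTo))  # re-derive the PCA distance space
      cs <- preprocessCells(cs, minExpressingFraction = 0,
                            logTransform = FALSE,
                            reduceTo = cfg$io.reduceTo)
    ordDf <- utils::read.csv(ordPath)
    # rebuild the random-walk state deterministically from the ordering
    recon <- .reconstructOrdering(ordDf, cs, cfg)
  }

  if (stage == "landscape") {
    g <- .solveWalk(recon, cs, cfg)
    E <- cellPotentials(g)
    perCell <- data.frame(cell_id = cellIds(cs),
                          p = stationaryProbs(g), E = E)
    surf <- buildLandscapeSurface(
      E, cs, tree = recon$tree,
      gridResolution = cfg$landscape.gridResolution,
      smoothingBandwidth = cfg$landscape.smoothingBandwidth)
    perCell$embed_x <- surf@embedding[, 1L]
    perCell$embed_y <- surf@embedding[, 2L]
    utils::write.csv(perCell, .artifact(runDir, "cell-potentials.csv"),
                     row.names = FALSE)
    utils::write.table(surf@values,
                       .artifact(runDir, "surface-grid.tsv"),
                       sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(
      list(grid_x = range(surf@gridX), grid_y = range(surf@gridY),
           resolution = cfg$landscape.gridResolution,
           bandwidth = cfg$landscape.smoothingBandwidth,
           method = "pca"),
      .artifact(runDir, "surface-meta.json"), auto_unbox = TRUE,
      digits = NA)
    written <- c(written, "cell-potentials.csv", "surface-grid.tsv",
                 "surface-meta.json")
    logLine("landscape solved; potential range",
            paste(format(range(E), digits = 4), collapse = " .. "))
  }

  if (stage == "dynamics") {
    potPath <- .needArtifact(runDir, "cell-potentials.csv", "landscape")
    E <- utils::read.csv(potPath)$E
    g <- .solveWalk(recon, cs, cfg)
    assignment <- assignCellTypes(recon$ordering)
    assignment <- detectSubtypeWells(assignment, E, recon$ordering,
                                     window = cfg$dynamics.subtypeWindow,
                                     barrierMin = cfg$dynamics.barrierMin)
    rates <- linkVisitRates(g)
    dyn <- cellTypeDynamics(rates, assignment)
    utils::write.csv(
      data.frame(cell_id = cellIds(cs), type_id = cellTypes(assignment),
                 subtype_id = cellSubtypes(assignment)),
      .artifact(runDir, "cell-types.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(q_matrix = transitionMatrix(dyn), q_exit = exitProbs(dyn),
           fate = fateProbs(dyn)),
      .artifact(runDir, "dynamics.json"), digits = NA)
    written <- c(written, "cell-types.csv", "dynamics.json")
    logLine("dynamics over", assignment@nTypes, "types")
  }

  if (stage == "network") {
    windows <- makePseudotimeWindows(
      recon$ordering, nWindows = cfg$network.nWindows,
      overlapFraction = cfg$network.overlapFraction,
      perBranch = cfg$network.perBranch,
      minCellsPerWindow = cfg$network.minCellsPerWindow)
    panel <- .topVariancePanel(cs, cfg$network.panelSize)
    traj <- correlationTrajectory(windows, cs, panel,
                                  ratioFloor = cfg$network.ratioFloor)
    utils::write.csv(traj, .artifact(runDir, "correlation-degrees.csv"),
                     row.names = FALSE)
    core <- cfg$network.coreGene
    if (!is.na(core) && !core %in% panel) panel <- c(panel, core)
    for (wi in seq_along(windows)) {
      grn <- inferGRNWindow(windows[[wi]], cs, panel,
                            nTrees = cfg$network.nTrees,
                            seed = cfg$seed + 1000L * wi)
      utils::write.csv(grn,
                       .artifact(runDir,
                                 sprintf("grn-window%02d.csv", wi)))
      if (!is.na(core)) {
        nb <- extractNeighborhood(grn, cs, windows[[wi]], core,
                                  kPartners = cfg$network.kPartners,
                                  mutualThreshold =
                                    cfg$network.mutualThreshold)
        utils::write.csv(
          data.frame(gene = c(nb$core, nb$partners),
                     role = c("core",
                              rep("partner", length(nb$partners)))),
          .artifact(runDir,
                    sprintf("neighborhood-nodes-window%02d.csv", wi)),
          row.names = FALSE)
        edges <- if (is.null(nb$edges))
          data.frame(gene1 = character(0), gene2 = character(0),
                     abs_cor = numeric(0)) else nb$edges
        utils::write.csv(
          edges,
          .artifact(runDir,
                    sprintf("neighborhood-edges-window%02d.csv", wi)),
          row.names = FALSE)
        written <- c(written,
                     sprintf("neighborhood-nodes-window%02d.csv", wi),
                     sprintf("neighborhood-edges-window%02d.csv", wi))
      }
    }
    written <- c(written, "correlation-degrees.csv",
                 sprintf("grn-window%02d.csv", seq_along(windows)))
    logLine("network over", length(windows), "windows")
  }

  if (stage == "burst") {
    windows <- makePseudotimeWindows(
      recon$ordering, nWindows = cfg$network.nWindows,
      overlapFraction = cfg$network.overlapFraction,
      perBranch = cfg$network.perBranch,
      minCellsPerWindow = cfg$network.minCellsPerWindow)
    bt <- burstTrajectories(cs, recon$ordering, windows,
                            minObs = cfg$burst.minObs,
                            bfThreshold = cfg$burst.bfThreshold,
                            bsThreshold = cfg$burst.bsThreshold,
                            thresholdMode = cfg$burst.thresholdMode)
    utils::write.csv(bt$fits, .artifact(runDir, "burst-fits.csv"),
                     row.names = FALSE)
    utils::write.csv(bt$summary,
                     .artifact(runDir, "burst-summary.csv"),
                     row.names = FALSE)
    written <- c(written, "burst-fits.csv", "burst-summary.csv")
    logLine("burst fits over", length(windows), "windows")
  }

  # update the manifest (deterministic: config + completed stages)
  manifestPath <- .artifact(runDir, "run-manifest.json")
  stages <- character(0)
  if (file.exists(manifestPath))
    stages <- unlist(jsonlite::read_json(manifestPath)$stages)
  stages <- unique(c(stages, stage))
  .writeManifest(runDir, cfg, stages)
  invisible(file.path(runDir, written))
}

# Rebuild a CellOrdering (tree included) from the ordering.csv artifact
# plus the deterministic re-grown tree. Stages downstream of 'backbone'
# need chain/tree metadata; rather than serializing the full object the
# backbone computation is repeated (it is deterministic and cheap
# relative to its outputs).
.reconstructOrdering <- function(ordDf, cs, ctxCfg) {
  ctx <- deriveSigma(cs, ctxCfg$io.sigmaQuantile)
  field <- computePseudoPotential(cs, ctx)
  params <- backboneParams(
    baseRadiusFactor = ctxCfg$backbone.baseRadiusFactor,
    halfWidthFactor = ctxCfg$backbone.halfWidthFactor,
    minRingCells = ctxCfg$backbone.minRingCells,
    radiusGrowth = ctxCfg$backbone.radiusGrowth,
    deltaMinFactor = ctxCfg$backbone.deltaMinFactor,
    excludeFactor = ctxCfg$backbone.excludeFactor,
    mergeFactor = ctxCfg$backbone.mergeFactor,
    maxDepth = ctxCfg$backbone.maxDepth,
    minCellsTotal = ctxCfg$backbone.minCellsTotal)
  tree <- growBackboneTree(cs, field, params = params)
  if (ctxCfg$backbone.nSubdivisions > 0L)
    tree <- refineBackboneTree(tree, field, cs,
                               nSubdivisions =
                                 ctxCfg$backbone.nSubdivisions)
  ordering <- projectCells(tree, cs)
  # sanity: the reconstruction must agree with the artifact
  if (max(abs(ordering@pseudotime - ordDf$pseudotime)) > 1e-8)
    stop("ordering artifact does not match this configuration: ",
         "re-run the 'backbone' stage")
  list(ordering = ordering, field = field, tree = tree)
}

.solveWalk <- function(recon, cs, cfg) {
  g <- buildWeightGraph(recon$ordering, cs, chi = cfg$landscape.chi,
                        kNeighbors = cfg$landscape.kNeighbors,
                        W0 = cfg$landscape.W0)
  g <- conditionalProbabilities(g)
  stationaryDistribution(g, epsilon = cfg$landscape.epsilon,
                         tol = cfg$landscape.tol,
                         maxIter = cfg$landscape.maxIter,
                         teleport = cfg$landscape.teleport)
}

.topVariancePanel <- function(cs, k) {
  v <- exprValues(cs)
  vars <- apply(v, 2L, var)
  names(sort(vars, decreasing = TRUE))[seq_len(min(k, length(vars)))]
}
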