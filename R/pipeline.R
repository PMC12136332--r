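#' Assemble a full pipeline configuration
#'
#' Collects every tunable of the end-to-end run — windowing, FC order,
#' edge selection, graph features, model and training — with the package
#' defaults. Unknown arguments are rejected. Either `manifest` (a cohort
#' on disk) or `simSpec` (a synthetic cohort) must be given to run.
#'
#' @param manifest path to a cohort manifest (see [readCohort()]), or NULL.
#' @param simSpec a [SimSpec-class] to simulate the cohort, or NULL.
#' @param L,s sliding-window length and step (defaults 30 and 2).
#' @param fcOrder `"low"` or `"high"`.
#' @param pThreshold edge-selection significance level (default 0.05).
#' @param welch,perWindowStack see [fitEdgeMask()].
#' @param negativePolicy,eq3Literal see [normalizeAdjacency()] and
#'   [localClustering()].
#' @param highOrderCentered see [buildHighOrder()].
#' @param partition optional path to a region-network partition CSV, or a
#'   partition vector ([makePartition()]); enables the ablation stage.
#' @param outDir optional output directory; when given, every artifact
#'   (resolved config, mask, metrics, history) is written under a
#'   timestamped run directory inside it.
#' @param seed master seed for split, initialization, batching, dropout.
#' @param verbose emit one structured log line per stage?
#' @param ... overrides forwarded to [trainConfig()] (e.g. `epochs`,
#'   `dropout`, `lstmHidden`).
#' @return a named list (class `dwgnnRunConfig`).
#' @export
runConfig <- function(manifest = NULL, simSpec = NULL, L = 30L, s = 2L,
                      fcOrder = c("low", "high"), pThreshold = 0.05,
                      welch = FALSE, perWindowStack = FALSE,
                      negativePolicy = "abs", eq3Literal = FALSE,
                      highOrderCentered = FALSE, partition = NULL,
                      outDir = NULL, seed = 1L, verbose = FALSE, ...) {
  fcOrder <- match.arg(fcOrder)
  train <- trainConfig(seed = seed, ...)
  cfg <- list(manifest = manifest, simSpec = simSpec, L = as.integer(L),
              s = as.integer(s), fcOrder = fcOrder, pThreshold = pThreshold,
              welch = welch, perWindowStack = perWindowStack,
              negativePolicy = negativePolicy, eq3Literal = eq3Literal,
              highOrderCentered = highOrderCentered, partition = partition,
              outDir = outDir, seed = as.integer(seed), verbose = verbose,
              train = train)
  class(cfg) <- "dwgnnRunConfig"
  cfg
}

subsetFCSet <- function(fcset, idx) {
  new("DynamicFCSet", fc = fcset@fc[idx],
      labels = droplevels(factor(fcset@labels[idx], levels = GROUP_LEVELS)))
}

reportToList <- function(report) {
  list(counts = as.list(confusionCounts(report)),
       metrics = as.list(metricValues(report)))
}

resolvedConfigList <- function(config) {
  out <- unclass(config)
  out$train <- unclass(out$train)
  if (!is.null(out$simSpec)) {
    sp <- out$simSpec
    out$simSpec <- list(n_regions = sp@nRegions, n_timepoints = sp@nTimepoints,
                        n_per_group = sp@nPerGroup,
                        effect_edges = sp@effectEdges,
                        effect_size = sp@effectSize, n_states = sp@nStates,
                        switch_prob = sp@switchProb, noise_sd = sp@noiseSd,
                        seed = sp@seed)
  }
  out
}

#' Run the full classification pipeline
#'
#' Executes, in order: cohort acquisition (simulation or manifest),
#' sliding-window low-order FC, optionally high-order FC, t-test edge-mask
#' fitting on the training split only, mask application, graph-sequence
#' construction (clustering-coefficient node features + normalized
#' weighted adjacency), GCN-LSTM training with validation-based early
#' stopping, held-out test evaluation, and — when a partition is supplied —
#' the per-network ablation table. The whole run is a pure function of the
#' configuration (including its seed).
#'
#' @param config a [runConfig()] list.
#' @return list with `report` (test-set [MetricReport-class]), `model`,
#'   `mask`, `split`, `history`, `ablation` (data.frame or NULL) and
#'   `runDir` (NULL unless `outDir` was set).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "dwgnnRunConfig"))
  v <- config$verbose
  t0 <- Sys.time()

  if (!is.null(config$simSpec)) {
    cohort <- makeCohort(config$simSpec)
    stageLog(v, "simulate", "%d subjects, R=%d", nSubjects(cohort),
             nRegions(cohort))
  } else if (!is.null(config$manifest)) {
    cohort <- readCohort(config$manifest)
    stageLog(v, "read", "%d subjects, R=%d from %s", nSubjects(cohort),
             nRegions(cohort), config$manifest)
  } else stop("config needs either a manifest or a simSpec")

  labels <- groupLabels(cohort)
  split <- stratifiedSplit(labels, config$train$split, config$seed)

  fcset <- buildLowOrder(cohort, L = config$L, s = config$s)
  if (config$fcOrder == "high")
    fcset <- buildHighOrder(fcset, centered = config$highOrderCentered)
  K <- nWindows(fcset@fc[[1]])
  stageLog(v, "dynfc", "%s-order, K=%d windows", config$fcOrder, K)

  mask <- fitEdgeMask(subsetFCSet(fcset, split$train),
                      pThreshold = config$pThreshold, welch = config$welch,
                      perWindowStack = config$perWindowStack)
  up <- upper.tri(maskKeep(mask))
  stageLog(v, "edge_select", "%d/%d edges kept (train-only fit)",
           sum(maskKeep(mask)[up]), sum(up))

  masked <- applyEdgeMask(fcset, mask)
  seqs <- buildGraphSequence(masked, negativePolicy = config$negativePolicy,
                             eq3Literal = config$eq3Literal)
  stageLog(v, "graph_features", "features %dx%d per subject", K,
           nRegions(fcset))

  model <- trainModel(seqs, labels, config$train, split = split)
  stageLog(v, "train", "stopped after %d epochs (best %d)",
           nrow(model@history), model@config$bestEpoch)

  report <- evaluateModel(model, seqs[split$test], labels[split$test])
  stageLog(v, "evaluate", "test ACC %.2f%% on %d subjects",
           metricValues(report)["ACC"], length(split$test))

  ablation <- NULL
  if (!is.null(config$partition)) {
    part <- if (is.character(config$partition) &&
                length(config$partition) == 1 &&
                file.exists(config$partition))
      readPartition(config$partition, nRegions(fcset))
    else config$partition
    ablation <- ablationTable(subsetFCSet(masked, split$test),
                              labels[split$test], part, model,
                              negativePolicy = config$negativePolicy,
                              eq3Literal = config$eq3Literal)
    stageLog(v, "ablate", "%d networks ablated", nrow(ablation))
  }

  runDir <- NULL
  if (!is.null(config$outDir)) {
    stamp <- format(t0, "run_%Y%m%d_%H%M%S")
    runDir <- file.path(config$outDir, stamp)
    dir.create(runDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(resolvedConfigList(config),
                         file.path(runDir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    writeEdgeMask(mask, file.path(runDir, "edge_mask"))
    jsonlite::write_json(reportToList(report),
                         file.path(runDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(model@history, file.path(runDir, "history.csv"),
                     row.names = FALSE)
    if (!is.null(ablation))
      utils::write.csv(ablation, file.path(runDir, "ablation.csv"),
                       row.names = FALSE)
    stageLog(v, "artifacts", "written to %s", runDir)
  }

  list(report = report, model = model, mask = mask, split = split,
       history = model@history, ablation = ablation, runDir = runDir,
       maskedFc = masked, seqs = seqs, labels = labels)
}
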