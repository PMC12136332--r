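## Zero every FC edge incident to the given regions, in every window.
## The diagonal is untouched: the self-loop augmented adjacency downstream
## keeps the graph well-defined for the ablated regions.
ablateRegionsFC <- function(fc, regions) {
  mats <- lapply(fc@matrices, function(m) {
    d <- diag(m)
    m[regions, ] <- 0
    m[, regions] <- 0
    diag(m) <- d
    m
  })
  new("DynamicFC", subjectId = fc@subjectId, order = fc@order,
      matrices = mats)
}

#' Re-evaluate a trained model with one resting-state network removed
#'
#' Operationalizes the "remove the features of one network" probe: every
#' edge incident to a region of the named network is zeroed in the masked
#' FC of each test subject, the graph sequence (clustering-coefficient
#' node features and normalized adjacency) is recomputed on the ablated
#' graphs — so the ablated regions' features drop to zero and their
#' influence on message passing disappears — and the already-trained model
#' is re-evaluated without retraining.
#'
#' @param maskedFc [DynamicFCSet-class] of the evaluation subjects, already
#'   edge-masked (the same preprocessing the model was trained with).
#' @param labels factor with levels `NC`, `eMCI` aligned with `maskedFc`.
#' @param partition region-to-network labels, see [makePartition()].
#' @param network network label to remove (must occur in `partition` or be
#'   assigned to no region, which is a no-op).
#' @param model trained [DwGnnModel-class].
#' @param baseline optional baseline [MetricReport-class] on the intact
#'   graphs; computed on the fly when omitted.
#' @param negativePolicy,eq3Literal forwarded to [buildGraphSequence()].
#' @return list with `report` (the degraded [MetricReport-class]),
#'   `baseline` and `deltaAcc` (baseline accuracy minus ablated accuracy,
#'   in percentage points).
#' @export
ablateNetwork <- function(maskedFc, labels, partition, network, model,
                          baseline = NULL, negativePolicy = "abs",
                          eq3Literal = FALSE) {
  stopifnot(is(maskedFc, "DynamicFCSet"))
  if (length(partition) != nRegions(maskedFc))
    stop(sprintf("partition covers %d regions, cohort has %d",
                 length(partition), nRegions(maskedFc)))
  knownNetworks <- unique(partition)
  if (!network %in% knownNetworks)
    stop(sprintf("unknown network label '%s' (known: %s)", network,
                 paste(knownNetworks, collapse = ", ")))
  regions <- which(partition == network)
  if (is.null(baseline)) {
    seqs0 <- buildGraphSequence(maskedFc, negativePolicy = negativePolicy,
                                eq3Literal = eq3Literal)
    baseline <- evaluateModel(model, seqs0, labels)
  }
  ablFc <- new("DynamicFCSet",
               fc = lapply(maskedFc@fc, ablateRegionsFC, regions = regions),
               labels = maskedFc@labels)
  seqs <- buildGraphSequence(ablFc, negativePolicy = negativePolicy,
                             eq3Literal = eq3Literal)
  report <- evaluateModel(model, seqs, labels)
  list(report = report, baseline = baseline,
       deltaAcc = unname(metricValues(baseline)["ACC"] -
                         metricValues(report)["ACC"]))
}

#' Ablation table over all resting-state networks
#'
#' Runs [ablateNetwork()] for every network label in the partition and
#' tabulates accuracy and its drop against the intact baseline.
#'
#' @inheritParams ablateNetwork
#' @return data.frame with columns `network`, `ACC`, `deltaACC` plus the
#'   baseline accuracy as attribute `baselineACC`.
#' @export
ablationTable <- function(maskedFc, labels, partition, model,
                          negativePolicy = "abs", eq3Literal = FALSE) {
  seqs0 <- buildGraphSequence(maskedFc, negativePolicy = negativePolicy,
                              eq3Literal = eq3Literal)
  baseline <- evaluateModel(model, seqs0, labels)
  nets <- unique(partition)
  rows <- lapply(nets, function(nw) {
    res <- ablateNetwork(maskedFc, labels, partition, nw, model,
                         baseline = baseline,
                         negativePolicy = negativePolicy,
                         eq3Literal = eq3Literal)
    data.frame(network = nw, ACC = metricValues(res$report)["ACC"],
               deltaACC = res$deltaAcc, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "baselineACC") <- unname(metricValues(baseline)["ACC"])
  out
}
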