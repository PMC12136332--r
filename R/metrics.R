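#' Confusion counts from true and predicted labels
#'
#' @param truth,predicted factors with levels `NC`, `eMCI`; eMCI is the
#'   positive class.
#' @return named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusionFromLabels <- function(truth, predicted) {
  truth <- factor(truth, levels = GROUP_LEVELS)
  predicted <- factor(predicted, levels = GROUP_LEVELS)
  stopifnot(length(truth) == length(predicted), !anyNA(truth),
            !anyNA(predicted))
  c(TP = sum(truth == "eMCI" & predicted == "eMCI"),
    TN = sum(truth == "NC" & predicted == "NC"),
    FP = sum(truth == "NC" & predicted == "eMCI"),
    FN = sum(truth == "eMCI" & predicted == "NC"))
}

#' Classification metrics from confusion counts
#'
#' The six standard indicators, as percentages: sensitivity
#' TPR = TP/(TP+FN), specificity TNR = TN/(TN+FP), precision
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN), accuracy
#' ACC = (TP+TN)/(TP+TN+FP+FN) and F1 = 2TP/(2TP+FN+FP). A metric with a
#' zero denominator is reported as `NA` (undefined), never an error.
#'
#' @param counts named vector with nonnegative `TP`, `TN`, `FP`, `FN` (at
#'   least one test subject in total).
#' @return a [MetricReport-class].
#' @examples
#' computeMetrics(c(TP = 3, TN = 2, FP = 1, FN = 0))
#' @export
computeMetrics <- function(counts) {
  counts <- counts[c("TP", "TN", "FP", "FN")]
  if (anyNA(counts)) stop("counts must contain TP, TN, FP, FN")
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  if (sum(counts) < 1) stop("at least one test subject is required")
  counts <- stats::setNames(as.integer(counts), c("TP", "TN", "FP", "FN"))
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  TP <- counts["TP"]; TN <- counts["TN"]; FP <- counts["FP"]; FN <- counts["FN"]
  metrics <- c(
    TPR = ratio(TP, TP + FN),
    TNR = ratio(TN, TN + FP),
    PPV = ratio(TP, TP + FP),
    NPV = ratio(TN, TN + FN),
    ACC = ratio(TP + TN, TP + TN + FP + FN),
    F1 = ratio(2 * TP, 2 * TP + FN + FP))
  names(metrics) <- c("TPR", "TNR", "PPV", "NPV", "ACC", "F1")
  new("MetricReport", counts = counts, metrics = metrics)
}

#' Read a region-to-network partition table
#'
#' Two-column delimited table (`region_index`, `network_label`) assigning
#' every region to exactly one resting-state network (e.g. DMN, EAN, VN,
#' SMN, SR, CER). Region indices are 1-based.
#'
#' @param path file path (CSV with header).
#' @param nRegionsExpected optional check on the number of regions covered.
#' @return named character vector: element i is region i's network label.
#' @export
readPartition <- function(path, nRegionsExpected = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("partition table needs columns region_index, network_label")
  names(df)[1:2] <- c("region_index", "network_label")
  makePartition(df$region_index, df$network_label, nRegionsExpected)
}

#' Build a region-to-network partition vector
#'
#' @param regionIndex 1-based region indices.
#' @param networkLabel network label per region.
#' @param nRegionsExpected optional total region count to validate against.
#' @return character vector of length `max(regionIndex)`; element i is
#'   region i's network label.
#' @export
makePartition <- function(regionIndex, networkLabel, nRegionsExpected = NULL) {
  regionIndex <- as.integer(regionIndex)
  if (anyDuplicated(regionIndex))
    stop("every region must be assigned exactly one network label")
  n <- max(regionIndex)
  if (!is.null(nRegionsExpected) && n != nRegionsExpected)
    stop(sprintf("partition covers %d regions, expected %d",
                 n, nRegionsExpected))
  if (!identical(sort(regionIndex), seq_len(n)))
    stop("partition must cover every region index 1..R exactly once")
  out <- character(n)
  out[regionIndex] <- as.character(networkLabel)
  out
}
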