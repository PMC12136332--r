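#' @import methods
#' @importFrom Matrix bdiag
#' @importFrom Rcpp sourceCpp
#' @useDynLib dwgnn, .registration = TRUE
NULL

GROUP_LEVELS <- c("NC", "eMCI")

#' Cohort of ROI time-series matrices
#'
#' Holds one BOLD time-series matrix per subject (rows = regions, columns =
#' time points) together with binary diagnostic labels. All subjects must
#' share the region count; series length may vary per subject.
#'
#' @slot series list of numeric region x time matrices, one per subject.
#' @slot labels factor with levels `NC` and `eMCI`, one per subject.
#' @slot subjectIds character vector of unique subject identifiers.
#'
#' @seealso [makeCohort()], [readCohort()], [buildLowOrder()]
#' @export
setClass("RoiTimeSeriesSet",
  representation(series = "list", labels = "factor", subjectIds = "character"))

setValidity("RoiTimeSeriesSet", function(object) {
  n <- length(object@series)
  if (length(object@labels) != n || length(object@subjectIds) != n)
    return("series, labels and subjectIds must have equal length")
  if (anyDuplicated(object@subjectIds))
    return("subjectIds must be unique")
  if (!identical(levels(object@labels), GROUP_LEVELS))
    return("labels must be a factor with levels NC, eMCI")
  if (anyNA(object@labels))
    return("labels must not contain NA")
  if (n > 0) {
    if (!all(vapply(object@series, function(m) is.matrix(m) && is.numeric(m),
                    logical(1))))
      return("every series must be a numeric matrix")
    rr <- vapply(object@series, nrow, integer(1))
    if (length(unique(rr)) > 1)
      return(sprintf("all subjects must share the region count (saw: %s)",
                     paste(unique(rr), collapse = ", ")))
  }
  TRUE
})

#' Dynamic functional connectivity network of one subject
#'
#' A length-K sequence of symmetric R x R functional connectivity matrices
#' obtained from sliding windows, either low-order (windowed Pearson
#' correlation of BOLD signals) or high-order (cosine similarity between
#' columns of the low-order matrix).
#'
#' @slot subjectId character scalar.
#' @slot order `"low"` or `"high"`.
#' @slot matrices list of K symmetric R x R matrices with entries in [-1, 1].
#'
#' @seealso [buildLowOrder()], [buildHighOrder()], [applyEdgeMask()]
#' @export
setClass("DynamicFC",
  representation(subjectId = "character", order = "character",
                 matrices = "list"))

setValidity("DynamicFC", function(object) {
  if (length(object@order) != 1L || !object@order %in% c("low", "high"))
    return("order must be \"low\" or \"high\"")
  if (length(object@matrices) < 1L)
    return("at least one window is required")
  dims <- vapply(object@matrices, function(m) dim(m), integer(2))
  if (any(dims != dims[1, 1]))
    return("all windows must be square matrices of equal size")
  TRUE
})

#' Cohort-level container of dynamic FC networks
#'
#' @slot fc list of [DynamicFC-class] objects sharing region count and order.
#' @slot labels factor with levels `NC` and `eMCI`, aligned with `fc`.
#' @export
setClass("DynamicFCSet", representation(fc = "list", labels = "factor"))

setValidity("DynamicFCSet", function(object) {
  if (length(object@fc) != length(object@labels))
    return("fc and labels must align")
  if (!identical(levels(object@labels), GROUP_LEVELS))
    return("labels must be a factor with levels NC, eMCI")
  ord <- unique(vapply(object@fc, function(f) f@order, character(1)))
  if (length(ord) > 1) return("all subjects must share the FC order")
  rr <- unique(vapply(object@fc, function(f) nrow(f@matrices[[1]]), integer(1)))
  if (length(rr) > 1) return("all subjects must share the region count")
  TRUE
})

#' Edge mask from two-sample t-tests
#'
#' Symmetric boolean matrix of retained functional connectivity edges,
#' fitted on training subjects only: for each edge the per-subject statistic
#' (the edge's FC averaged over windows) is compared between groups by a
#' two-sided two-sample t-test and the edge is kept when p < pThreshold.
#'
#' @slot keep symmetric logical R x R matrix (diagonal TRUE by convention;
#'   the diagonal is never tested and survives for the self-loop augmented
#'   adjacency downstream).
#' @slot pValues symmetric numeric R x R matrix in [0, 1] (diagonal NA).
#' @slot pThreshold significance level, default 0.05.
#' @slot fittedOn subject ids of the training subjects used for fitting.
#' @slot order FC order the mask was fitted on.
#' @seealso [fitEdgeMask()], [applyEdgeMask()]
#' @export
setClass("EdgeMask",
  representation(keep = "matrix", pValues = "matrix", pThreshold = "numeric",
                 fittedOn = "character", order = "character"))

setValidity("EdgeMask", function(object) {
  if (!is.logical(object@keep) || !isSymmetric(object@keep))
    return("keep must be a symmetric logical matrix")
  if (!identical(dim(object@keep), dim(object@pValues)))
    return("keep and pValues must have identical dimensions")
  off <- object@pValues[row(object@pValues) != col(object@pValues)]
  if (any(off < 0 | off > 1, na.rm = TRUE))
    return("p-values must lie in [0, 1]")
  if (object@pThreshold <= 0 || object@pThreshold > 1)
    return("pThreshold must lie in (0, 1]")
  TRUE
})

#' Per-subject graph sequence fed to the classifier
#'
#' Pairs, for every window k, the symmetrically normalized self-loop
#' augmented weighted adjacency D^-1/2 (A + I) D^-1/2 with the vector of
#' weighted-graph local clustering coefficients used as node features.
#'
#' @slot subjectId character scalar.
#' @slot nodeFeatures K x R matrix of clustering coefficients in [0, 1].
#' @slot normAdj list of K symmetric R x R normalized adjacency matrices.
#' @seealso [buildGraphSequence()], [trainModel()]
#' @export
setClass("GraphSequence",
  representation(subjectId = "character", nodeFeatures = "matrix",
                 normAdj = "list"))

setValidity("GraphSequence", function(object) {
  K <- nrow(object@nodeFeatures)
  if (length(object@normAdj) != K)
    return("normAdj must have one matrix per feature row")
  if (K > 0 && ncol(object@nodeFeatures) != nrow(object@normAdj[[1]]))
    return("feature columns must match adjacency size")
  f <- object@nodeFeatures
  if (any(f < -1e-9 | f > 1 + 1e-9))
    return("node features must lie in [0, 1]")
  TRUE
})

#' Confusion counts and derived classification metrics
#'
#' Confusion-matrix counts with eMCI as the positive class, plus the six
#' standard derived metrics (TPR, TNR, PPV, NPV, ACC, F1) expressed as
#' percentages in [0, 100]. Zero-denominator metrics are `NA` (undefined),
#' never an error.
#'
#' @slot counts named integer vector `TP`, `TN`, `FP`, `FN`.
#' @slot metrics named numeric vector `TPR`, `TNR`, `PPV`, `NPV`, `ACC`,
#'   `F1` in percent; `NA` marks an undefined (zero-denominator) metric.
#' @seealso [computeMetrics()], [ablateNetwork()]
#' @export
setClass("MetricReport",
  representation(counts = "integer", metrics = "numeric"))

setValidity("MetricReport", function(object) {
  if (!identical(names(object@counts), c("TP", "TN", "FP", "FN")))
    return("counts must be named TP, TN, FP, FN")
  if (any(object@counts < 0)) return("counts must be nonnegative")
  if (!identical(names(object@metrics),
                 c("TPR", "TNR", "PPV", "NPV", "ACC", "F1")))
    return("metrics must be named TPR, TNR, PPV, NPV, ACC, F1")
  TRUE
})

#' Specification of a synthetic two-group cohort
#'
#' Parameters of the Markov state-switching multivariate-normal generator
#' used to emulate ROI-level BOLD series of a control (NC) and an early-MCI
#' (eMCI) group. The eMCI group differs from NC only on `effectEdges`, whose
#' state correlations are reduced by `effectSize` (hypoconnectivity).
#'
#' @slot nRegions number of regions R (default 116, the AAL atlas size).
#' @slot nTimepoints series length M (default 137, i.e. 140 acquired volumes
#'   with the first 3 discarded for magnetization equilibrium).
#' @slot nPerGroup subjects per group.
#' @slot effectEdges integer matrix with two columns, one row per affected
#'   edge (unordered pairs of distinct 1-based region indices).
#' @slot effectSize correlation reduction magnitude in [0, 1).
#' @slot nStates number of latent covariance states.
#' @slot switchProb per-step probability of leaving the current state.
#' @slot noiseSd standard deviation of additive independent observation noise.
#' @slot seed integer master seed; the full cohort is a pure function of the
#'   specification.
#' @seealso [simSpec()], [simulateSubject()], [makeCohort()]
#' @export
setClass("SimSpec",
  representation(nRegions = "integer", nTimepoints = "integer",
                 nPerGroup = "integer", effectEdges = "matrix",
                 effectSize = "numeric", nStates = "integer",
                 switchProb = "numeric", noiseSd = "numeric",
                 seed = "integer"))

setValidity("SimSpec", function(object) {
  if (object@nRegions < 2) return("nRegions must be >= 2")
  if (object@nTimepoints < 2) return("nTimepoints must be >= 2")
  if (object@nPerGroup < 1) return("nPerGroup must be >= 1")
  if (object@effectSize < 0 || object@effectSize >= 1)
    return("effectSize must lie in [0, 1)")
  if (object@switchProb < 0 || object@switchProb > 1)
    return("switchProb must lie in [0, 1]")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@nStates < 1) return("nStates must be >= 1")
  ee <- object@effectEdges
  if (nrow(ee) > 0) {
    if (ncol(ee) != 2) return("effectEdges must have two columns")
    if (any(ee < 1) || any(ee > object@nRegions))
      return("effectEdges indices must lie in 1..nRegions")
    if (any(ee[, 1] == ee[, 2]))
      return("effectEdges must pair distinct regions")
    key <- paste(pmin(ee[, 1], ee[, 2]), pmax(ee[, 1], ee[, 2]))
    if (anyDuplicated(key)) return("effectEdges must be unique unordered pairs")
  }
  TRUE
})

#' Trained dynamically weighted GCN-LSTM classifier
#'
#' @slot params list of learned parameters (GCN weight matrices, per-layer
#'   LSTM gate weights and biases, fully connected head).
#' @slot config resolved training configuration (see [trainConfig()]).
#' @slot history per-epoch data.frame of training/validation loss and
#'   accuracy.
#' @slot classLevels class labels, `c("NC", "eMCI")`.
#' @seealso [trainModel()], [predictModel()]
#' @export
setClass("DwGnnModel",
  representation(params = "list", config = "list", history = "data.frame",
                 classLevels = "character"))
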