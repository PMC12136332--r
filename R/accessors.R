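#' @rdname dwgnn-accessors
#' @export
setMethod("nRegions", "RoiTimeSeriesSet", function(x) {
  if (length(x@series) == 0L) return(0L)
  nrow(x@series[[1]])
})

#' @rdname dwgnn-accessors
#' @export
setMethod("nRegions", "DynamicFC", function(x) nrow(x@matrices[[1]]))

#' @rdname dwgnn-accessors
#' @export
setMethod("nRegions", "DynamicFCSet", function(x) nRegions(x@fc[[1]]))

#' @rdname dwgnn-accessors
#' @export
setMethod("nRegions", "EdgeMask", function(x) nrow(x@keep))

#' @rdname dwgnn-accessors
#' @export
setMethod("nRegions", "GraphSequence", function(x) ncol(x@nodeFeatures))

#' @rdname dwgnn-accessors
#' @export
setMethod("nSubjects", "RoiTimeSeriesSet", function(x) length(x@series))

#' @rdname dwgnn-accessors
#' @export
setMethod("nSubjects", "DynamicFCSet", function(x) length(x@fc))

#' @rdname dwgnn-accessors
#' @export
setMethod("nWindows", "DynamicFC", function(x) length(x@matrices))

#' @rdname dwgnn-accessors
#' @export
setMethod("nWindows", "GraphSequence", function(x) nrow(x@nodeFeatures))

#' @rdname dwgnn-accessors
#' @export
setMethod("subjectIds", "RoiTimeSeriesSet", function(x) x@subjectIds)

#' @rdname dwgnn-accessors
#' @export
setMethod("subjectIds", "DynamicFCSet",
  function(x) vapply(x@fc, function(f) f@subjectId, character(1)))

#' @rdname dwgnn-accessors
#' @export
setMethod("groupLabels", "RoiTimeSeriesSet", function(x) x@labels)

#' @rdname dwgnn-accessors
#' @export
setMethod("groupLabels", "DynamicFCSet", function(x) x@labels)

#' @rdname dwgnn-accessors
#' @export
setMethod("fcMatrices", "DynamicFC", function(x) x@matrices)

#' @rdname dwgnn-accessors
#' @export
setMethod("fcOrder", "DynamicFC", function(x) x@order)

#' @rdname dwgnn-accessors
#' @export
setMethod("fcOrder", "DynamicFCSet", function(x) x@fc[[1]]@order)

#' @rdname dwgnn-accessors
#' @export
setMethod("nodeFeatures", "GraphSequence", function(x) x@nodeFeatures)

#' @rdname dwgnn-accessors
#' @export
setMethod("normAdj", "GraphSequence", function(x) x@normAdj)

#' @rdname dwgnn-accessors
#' @export
setMethod("maskKeep", "EdgeMask", function(x) x@keep)

#' @rdname dwgnn-accessors
#' @export
setMethod("maskPValues", "EdgeMask", function(x) x@pValues)

#' @rdname dwgnn-accessors
#' @export
setMethod("metricValues", "MetricReport", function(x) x@metrics)

#' @rdname dwgnn-accessors
#' @export
setMethod("confusionCounts", "MetricReport", function(x) x@counts)

#' Extract one subject's dynamic FC network from a cohort
#'
#' @param x a [DynamicFCSet-class].
#' @param i subject index or subject id.
#' @param j,... unused.
#' @param drop unused.
#' @return a [DynamicFC-class].
#' @export
setMethod("[[", "DynamicFCSet", function(x, i, j, ...) {
  if (is.character(i)) i <- match(i, subjectIds(x))
  x@fc[[i]]
})

setMethod("show", "RoiTimeSeriesSet", function(object) {
  m <- vapply(object@series, ncol, integer(1))
  cat(sprintf("RoiTimeSeriesSet: %d subjects, %d regions\n",
              nSubjects(object), nRegions(object)))
  if (length(m)) {
    cat(sprintf("  series length: %s\n",
                if (length(unique(m)) == 1) unique(m)
                else sprintf("%d-%d", min(m), max(m))))
    print(table(object@labels))
  }
})

setMethod("show", "DynamicFC", function(object) {
  cat(sprintf("DynamicFC [%s-order]: subject %s, %d windows of %dx%d\n",
              object@order, object@subjectId, nWindows(object),
              nRegions(object), nRegions(object)))
})

setMethod("show", "DynamicFCSet", function(object) {
  cat(sprintf("DynamicFCSet [%s-order]: %d subjects, %d regions, K=%d\n",
              fcOrder(object), nSubjects(object), nRegions(object),
              nWindows(object@fc[[1]])))
  print(table(object@labels))
})

setMethod("show", "EdgeMask", function(object) {
  R <- nRegions(object)
  off <- upper.tri(object@keep)
  cat(sprintf(
    "EdgeMask [%s-order]: %d/%d edges kept at p < %g (fitted on %d subjects)\n",
    object@order, sum(object@keep[off]), sum(off), object@pThreshold,
    length(object@fittedOn)))
})

setMethod("show", "GraphSequence", function(object) {
  cat(sprintf("GraphSequence: subject %s, K=%d windows, %d regions\n",
              object@subjectId, nWindows(object), nRegions(object)))
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport (positive class: eMCI)\n")
  cat(sprintf("  counts: TP=%d TN=%d FP=%d FN=%d\n",
              object@counts["TP"], object@counts["TN"],
              object@counts["FP"], object@counts["FN"]))
  v <- object@metrics
  cat("  ", paste(sprintf("%s=%s", names(v),
                          ifelse(is.na(v), "undef", sprintf("%.2f%%", v))),
                  collapse = " "), "\n", sep = "")
})

setMethod("show", "SimSpec", function(object) {
  cat(sprintf(
    "SimSpec: R=%d, M=%d, %d per group, %d states, effect %.2f on %d edges\n",
    object@nRegions, object@nTimepoints, object@nPerGroup, object@nStates,
    object@effectSize, nrow(object@effectEdges)))
})

setMethod("show", "DwGnnModel", function(object) {
  h <- object@history
  cat(sprintf("DwGnnModel: GCN widths %s, %d LSTM layers (hidden %d)\n",
              paste(object@config$gcnWidths, collapse = "-"),
              object@config$lstmLayers, object@config$lstmHidden))
  if (nrow(h)) {
    best <- which.min(h$valLoss)
    cat(sprintf("  trained %d epochs; best val loss %.4f (epoch %d), val acc %.3f\n",
                nrow(h), h$valLoss[best], best, h$valAcc[best]))
  }
})
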