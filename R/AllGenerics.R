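#' @name dwgnn-accessors
#' @title Accessors for dwgnn classes
#' @description Small generic accessors used across the package's S4
#'   containers: region/subject/window counts, subject ids, group labels and
#'   the underlying matrices.
#' @param x a dwgnn S4 object.
#' @return the accessed component; see the individual class pages.
NULL

#' @rdname dwgnn-accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname dwgnn-accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname dwgnn-accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' @rdname dwgnn-accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname dwgnn-accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname dwgnn-accessors
#' @export
setGeneric("fcMatrices", function(x) standardGeneric("fcMatrices"))

#' @rdname dwgnn-accessors
#' @export
setGeneric("fcOrder", function(x) standardGeneric("fcOrder"))

#' @rdname dwgnn-accessors
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))

#' @rdname dwgnn-accessors
#' @export
setGeneric("normAdj", function(x) standardGeneric("normAdj"))

#' @rdname dwgnn-accessors
#' @export
setGeneric("maskKeep", function(x) standardGeneric("maskKeep"))

#' @rdname dwgnn-accessors
#' @export
setGeneric("maskPValues", function(x) standardGeneric("maskPValues"))

#' @rdname dwgnn-accessors
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname dwgnn-accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
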