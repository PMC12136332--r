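#' Cut a time series into overlapping sliding windows
#'
#' Segments a region x time matrix into `K = floor((M - L) / s) + 1`
#' overlapping windows of length `L` with step `s`; window k (1-based)
#' covers columns `(k-1)*s + 1 .. (k-1)*s + L`. Trailing time points not
#' covered by a full window are dropped.
#'
#' @param series numeric region x time matrix (M columns).
#' @param L window length in time points (default 30).
#' @param s step size in time points (default 2).
#' @return list of K region x L matrices.
#' @examples
#' length(slideWindows(matrix(rnorm(2 * 137), 2), L = 30, s = 2))  # 54
#' @export
slideWindows <- function(series, L = 30L, s = 2L) {
  stopifnot(is.matrix(series), L >= 1, s >= 1)
  M <- ncol(series)
  if (L > M)
    stop(sprintf("window length L=%d exceeds series length M=%d", L, M))
  K <- (M - L) %/% s + 1L
  lapply(seq_len(K), function(k) {
    start <- (k - 1L) * s + 1L
    series[, start:(start + L - 1L), drop = FALSE]
  })
}

#' Number of sliding windows for a series length
#'
#' @param M series length; @param L window length; @param s step size.
#' @return integer window count `floor((M - L) / s) + 1`.
#' @export
windowCount <- function(M, L = 30L, s = 2L) {
  if (L > M)
    stop(sprintf("window length L=%d exceeds series length M=%d", L, M))
  as.integer((M - L) %/% s + 1L)
}

#' Discard initial volumes of a BOLD series
#'
#' Drops the first `n` time points of a region x time matrix (or of every
#' subject of a cohort), the usual guard against magnetization
#' non-equilibrium at scan start; e.g. 140 acquired volumes with `n = 3`
#' leave M = 137 retained time points.
#'
#' @param x region x time matrix or [RoiTimeSeriesSet-class].
#' @param n number of initial volumes to drop (default 3).
#' @return object of the same class with `n` fewer time points.
#' @export
discardInitialVolumes <- function(x, n = 3L) {
  if (is(x, "RoiTimeSeriesSet")) {
    x@series <- lapply(x@series, discardInitialVolumes, n = n)
    return(x)
  }
  stopifnot(is.matrix(x))
  if (n >= ncol(x))
    stop(sprintf("cannot drop %d of %d time points", n, ncol(x)))
  x[, -seq_len(n), drop = FALSE]
}

#' Windowed Pearson correlation between two segments
#'
#' Mean-centered (within the window) normalized inner product of two
#' equal-length segments — the low-order functional connectivity of a
#' region pair in one window. When either segment has zero variance the
#' correlation is undefined; the degenerate fallback value 0 is returned
#' with a warning.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1].
#' @export
lowOrderFC <- function(x, y) {
  if (length(x) != length(y))
    stop(sprintf("segment lengths differ (%d vs %d)", length(x), length(y)))
  stopifnot(length(x) >= 2)
  xc <- x - mean(x); yc <- y - mean(y)
  nx <- sqrt(sum(xc^2)); ny <- sqrt(sum(yc^2))
  if (nx == 0 || ny == 0) {
    warning("degenerate (constant) window segment; correlation set to 0")
    return(0)
  }
  max(-1, min(1, sum(xc * yc) / (nx * ny)))
}

## One window's full correlation matrix; zero-variance regions get 0 against
## all others and 1 on the diagonal (degenerate-window policy).
windowCorrelation <- function(segment) {
  sds <- apply(segment, 1, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  if (any(degenerate)) {
    warning(sprintf("%d region(s) with zero variance in a window; %s",
                    sum(degenerate), "their correlations set to 0"))
    C <- matrix(0, nrow(segment), nrow(segment))
    ok <- !degenerate
    if (sum(ok) >= 2)
      C[ok, ok] <- stats::cor(t(segment[ok, , drop = FALSE]))
  } else {
    C <- stats::cor(t(segment))
  }
  diag(C) <- 1
  pmax(pmin(symmetrize(C), 1), -1)
}

#' Build the low-order dynamic FC network
#'
#' Applies [slideWindows()] and computes, for every window, the full matrix
#' of pairwise windowed Pearson correlations. For a
#' [RoiTimeSeriesSet-class] this returns the cohort-level container; each
#' subject is windowed against its own series length.
#'
#' @param x numeric region x time matrix or a [RoiTimeSeriesSet-class].
#' @param L window length (default 30); @param s step size (default 2).
#' @param subjectId subject identifier (matrix input only).
#' @return a [DynamicFC-class] or [DynamicFCSet-class] with `order = "low"`.
#' @export
setGeneric("buildLowOrder",
  function(x, L = 30L, s = 2L, subjectId = "subject")
    standardGeneric("buildLowOrder"))

#' @rdname buildLowOrder
#' @export
setMethod("buildLowOrder", "matrix", function(x, L, s, subjectId) {
  segs <- slideWindows(x, L, s)
  new("DynamicFC", subjectId = subjectId, order = "low",
      matrices = lapply(segs, windowCorrelation))
})

#' @rdname buildLowOrder
#' @export
setMethod("buildLowOrder", "RoiTimeSeriesSet", function(x, L, s, subjectId) {
  fc <- lapply(seq_len(nSubjects(x)), function(i) {
    M <- ncol(x@series[[i]])
    if (L > M)
      stop(sprintf("subject %s: window length L=%d exceeds series length M=%d",
                   x@subjectIds[i], L, M))
    buildLowOrder(x@series[[i]], L, s, subjectId = x@subjectIds[i])
  })
  new("DynamicFCSet", fc = fc, labels = x@labels)
})

## Cosine similarity between the columns of one symmetric matrix; zero-norm
## columns get similarity 0 (degenerate fallback) and diagonal 1.
columnCosine <- function(C) {
  nrm <- sqrt(colSums(C^2))
  H <- crossprod(C)
  degenerate <- nrm == 0
  scale <- ifelse(degenerate, 1, nrm)
  H <- H / outer(scale, scale)
  if (any(degenerate)) {
    warning("zero-norm connectivity profile; high-order similarity set to 0")
    H[degenerate, ] <- 0
    H[, degenerate] <- 0
  }
  diag(H) <- 1
  pmax(pmin(symmetrize(H), 1), -1)
}

#' Build the high-order dynamic FC network
#'
#' For each window, computes the similarity between every two regions'
#' whole connectivity profiles — columns of the low-order FC matrix,
#' diagonal included. As printed in the source model this is the uncentered
#' cosine similarity; `centered = TRUE` switches to Pearson correlation of
#' the profiles for sensitivity analysis.
#'
#' @param low a [DynamicFC-class] or [DynamicFCSet-class] with order "low".
#' @param centered mean-center profiles before the inner product?
#' @return object of the same shape with `order = "high"`.
#' @export
setGeneric("buildHighOrder",
  function(low, centered = FALSE) standardGeneric("buildHighOrder"))

#' @rdname buildHighOrder
#' @export
setMethod("buildHighOrder", "DynamicFC", function(low, centered) {
  if (low@order != "low")
    stop("high-order FC must be built from a low-order network")
  mats <- lapply(low@matrices, function(C) {
    if (centered) {
      H <- suppressWarnings(stats::cor(C))
      H[!is.finite(H)] <- 0
      diag(H) <- 1
      pmax(pmin(symmetrize(H), 1), -1)
    } else columnCosine(C)
  })
  new("DynamicFC", subjectId = low@subjectId, order = "high",
      matrices = mats)
})

#' @rdname buildHighOrder
#' @export
setMethod("buildHighOrder", "DynamicFCSet", function(low, centered) {
  new("DynamicFCSet", fc = lapply(low@fc, buildHighOrder, centered = centered),
      labels = low@labels)
})
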