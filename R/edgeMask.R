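## Per-subject edge statistics: for each subject, each edge's FC averaged
## over its K windows (rows = subjects, columns = upper-triangle edges).
## With perWindowStack = TRUE every window contributes a row instead
## (samples are then autocorrelated across windows; off by default).
subjectEdgeStats <- function(fcset, perWindowStack = FALSE) {
  R <- nRegions(fcset)
  up <- upper.tri(matrix(0, R, R))
  rows <- lapply(fcset@fc, function(f) {
    vals <- vapply(f@matrices, function(m) m[up], numeric(sum(up)))
    if (perWindowStack) t(vals) else t(colMeans(t(vals)))
  })
  list(stats = do.call(rbind, rows), upper = up,
       groupSizes = if (perWindowStack)
         vapply(fcset@fc, nWindows, integer(1)) else NULL)
}

## Vectorised two-sample two-tailed t-test per column (edge). Classic
## pooled-variance Student by default; Welch optional. Zero-variance edges
## (zero pooled variance) get p = 1.
edgeTTest <- function(xA, xB, welch = FALSE) {
  nA <- nrow(xA); nB <- nrow(xB)
  mA <- colMeans(xA); mB <- colMeans(xB)
  vA <- apply(xA, 2, stats::var); vB <- apply(xB, 2, stats::var)
  if (welch) {
    se2 <- vA / nA + vB / nB
    df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    tstat <- (mA - mB) / sqrt(se2)
  } else {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    df <- rep(nA + nB - 2, length(sp2))
    tstat <- (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  bad <- !is.finite(tstat)
  if (any(bad)) {
    warning(sprintf("%d edge(s) with zero pooled variance; p set to 1",
                    sum(bad)))
    p[bad] <- 1
  }
  p
}

#' Fit an edge mask by per-edge two-sample t-tests
#'
#' For every edge (i < j), each training subject contributes one scalar:
#' that edge's FC averaged over its K windows. A two-sided two-sample
#' t-test across the NC/eMCI labels yields a p-value per edge; edges with
#' p < `pThreshold` are kept. No multiple-testing correction is applied
#' (single fixed threshold). Fit this on training subjects only and freeze
#' it — fitting on test subjects leaks their labels into the model.
#'
#' @param trainFc a [DynamicFCSet-class] of training subjects only.
#' @param pThreshold significance level (default 0.05).
#' @param welch use the unequal-variance (Welch) test instead of the
#'   pooled-variance Student test?
#' @param perWindowStack let every window contribute a sample instead of
#'   the per-subject window mean (samples then autocorrelated; default off).
#' @return an [EdgeMask-class]; the diagonal is kept by convention (it is
#'   never tested and is needed for the self-loop augmented adjacency).
#' @export
fitEdgeMask <- function(trainFc, pThreshold = 0.05, welch = FALSE,
                        perWindowStack = FALSE) {
  stopifnot(is(trainFc, "DynamicFCSet"))
  perGroup <- table(trainFc@labels)
  if (any(perGroup < 2))
    stop(sprintf("need >= 2 training subjects per label (have NC=%d, eMCI=%d)",
                 perGroup["NC"], perGroup["eMCI"]))
  es <- subjectEdgeStats(trainFc, perWindowStack)
  grp <- if (perWindowStack)
    rep(trainFc@labels, times = es$groupSizes) else trainFc@labels
  p <- edgeTTest(es$stats[grp == "NC", , drop = FALSE],
                 es$stats[grp == "eMCI", , drop = FALSE], welch = welch)
  R <- nRegions(trainFc)
  P <- matrix(NA_real_, R, R)
  P[es$upper] <- p
  P <- pmin(P, t(P), na.rm = TRUE)        # mirror upper triangle
  keep <- !is.na(P) & P < pThreshold
  diag(keep) <- TRUE
  diag(P) <- NA_real_
  new("EdgeMask", keep = keep, pValues = P, pThreshold = pThreshold,
      fittedOn = subjectIds(trainFc), order = fcOrder(trainFc))
}

#' Sparsify a dynamic FC network with a fitted edge mask
#'
#' Sets, in every window, the FC entries of removed edges to zero; the
#' diagonal is untouched and symmetry is preserved.
#'
#' @param fc a [DynamicFC-class] or [DynamicFCSet-class].
#' @param mask an [EdgeMask-class] with the same region count.
#' @return object of the same class, sparsified.
#' @export
setGeneric("applyEdgeMask", function(fc, mask) standardGeneric("applyEdgeMask"))

#' @rdname applyEdgeMask
#' @export
setMethod("applyEdgeMask", signature("DynamicFC", "EdgeMask"),
  function(fc, mask) {
    if (nRegions(fc) != nRegions(mask))
      stop(sprintf("region count mismatch: FC has %d, mask has %d",
                   nRegions(fc), nRegions(mask)))
    keep <- mask@keep
    diag(keep) <- TRUE
    new("DynamicFC", subjectId = fc@subjectId, order = fc@order,
        matrices = lapply(fc@matrices, function(m) m * keep))
  })

#' @rdname applyEdgeMask
#' @export
setMethod("applyEdgeMask", signature("DynamicFCSet", "EdgeMask"),
  function(fc, mask) {
    new("DynamicFCSet", fc = lapply(fc@fc, applyEdgeMask, mask = mask),
        labels = fc@labels)
  })

#' Persist / reload an edge mask
#'
#' The mask is written as a plain-text edge list (`i`, `j`, `p_value`,
#' `keep`; upper triangle, 1-based region indices) plus a JSON sidecar with
#' the threshold, FC order and training subject ids, and reloads bit-exactly.
#'
#' @param mask an [EdgeMask-class].
#' @param path basename for the two files (`<path>.edges.csv`,
#'   `<path>.json`).
#' @return `writeEdgeMask`: the path, invisibly. `readEdgeMask`: the mask.
#' @export
writeEdgeMask <- function(mask, path) {
  up <- which(upper.tri(mask@keep), arr.ind = TRUE)
  df <- data.frame(i = up[, 1], j = up[, 2],
                   p_value = sprintf("%.17g", mask@pValues[up]),
                   keep = mask@keep[up])
  utils::write.csv(df, paste0(path, ".edges.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(n_regions = nRegions(mask), p_threshold = mask@pThreshold,
         order = mask@order, fitted_on = mask@fittedOn),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEdgeMask
#' @export
readEdgeMask <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(path, ".edges.csv"))
  R <- meta$n_regions
  P <- matrix(NA_real_, R, R); keep <- matrix(FALSE, R, R)
  idx <- cbind(df$i, df$j)
  P[idx] <- as.numeric(df$p_value); P[idx[, 2:1]] <- as.numeric(df$p_value)
  keep[idx] <- df$keep; keep[idx[, 2:1]] <- df$keep
  diag(keep) <- TRUE
  new("EdgeMask", keep = keep, pValues = P, pThreshold = meta$p_threshold,
      fittedOn = as.character(meta$fitted_on), order = meta$order)
}
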