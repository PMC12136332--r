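#' Weighted-graph local clustering coefficients
#'
#' Triangle-intensity clustering coefficient of every node of a weighted
#' undirected graph (Onnela-style): with weights normalized to [0, 1] by
#' dividing by the largest weight, node i with neighbour set N(i) scores
#'
#'   n_i = 2 / (|N(i)| (|N(i)| - 1)) *
#'         sum over neighbour pairs j < h with A_jh != 0 of
#'         (w_ij w_ih w_jh)^(1/3)
#'
#' and 0 when it has fewer than two neighbours. Equal to the binary local
#' clustering coefficient when all retained weights equal the maximum.
#' Negative weights must be resolved (absolute value) before calling;
#' the diagonal must be zero.
#'
#' @param adj symmetric nonnegative R x R matrix, zero diagonal. Weights
#'   are max-normalized internally unless `normalize = FALSE`.
#' @param normalize divide weights by `max(adj)` first (default TRUE).
#' @param eq3Literal use the literal single-neighbour sum
#'   `2 * sum_j w_ij^(1/3) / (|N(i)| (|N(i)| - 1))` instead of the
#'   triangle-intensity form; kept for comparison only — it is not a
#'   clustering coefficient and is unbounded.
#' @return numeric vector of length R with entries in [0, 1] (triangle
#'   form).
#' @export
localClustering <- function(adj, normalize = TRUE, eq3Literal = FALSE) {
  stopifnot(is.matrix(adj))
  if (!isSymmetric(unname(adj)))
    stop("adjacency must be symmetric")
  if (any(diag(adj) != 0))
    stop("adjacency must have a zero diagonal for clustering coefficients")
  if (any(adj < 0)) stop("adjacency weights must be nonnegative")
  W <- adj
  mx <- max(W)
  if (normalize && mx > 0) W <- W / mx
  deg <- rowSums(W != 0)
  denom <- deg * (deg - 1)
  S <- W^(1 / 3)
  num <- if (eq3Literal) 2 * rowSums(S) else diag(S %*% S %*% S)
  out <- ifelse(denom > 0, num / denom, 0)
  unname(out)
}

#' Clustering-coefficient node features of a dynamic FC network
#'
#' For every window k the weighted local clustering coefficient of each
#' region, computed on the absolute masked FC with the diagonal removed and
#' weights max-normalized per window. Row k of the result is the node
#' feature vector handed to the graph convolution for window k.
#'
#' @param fc a (masked) [DynamicFC-class].
#' @param eq3Literal see [localClustering()].
#' @return K x R numeric matrix.
#' @export
nodeFeatureSequence <- function(fc, eq3Literal = FALSE) {
  stopifnot(is(fc, "DynamicFC"))
  t(vapply(fc@matrices, function(m) {
    A <- abs(m)
    diag(A) <- 0
    localClustering(A, normalize = TRUE, eq3Literal = eq3Literal)
  }, numeric(nRegions(fc))))
}

#' Symmetrically normalized self-loop augmented adjacency
#'
#' Builds, from one window's masked FC matrix, the operator used by the
#' graph convolution: negative entries are resolved by `negativePolicy`
#' (absolute value by default, or clipped to zero), the diagonal is
#' replaced by the identity self-loop (A~ = A + I), and the result is
#' symmetrically normalized as D~^(-1/2) A~ D~^(-1/2) with
#' D~_ii = sum_j A~_ij. For the nonnegative A~ this operator's eigenvalues
#' lie in [-1, 1].
#'
#' @param fcWindow symmetric R x R (masked) FC matrix.
#' @param negativePolicy `"abs"` (default) or `"clip_zero"`.
#' @return symmetric R x R matrix.
#' @export
normalizeAdjacency <- function(fcWindow, negativePolicy = c("abs", "clip_zero")) {
  negativePolicy <- match.arg(negativePolicy)
  stopifnot(is.matrix(fcWindow))
  if (!isSymmetric(unname(fcWindow)))
    stop("FC window must be symmetric")
  A <- switch(negativePolicy, abs = abs(fcWindow), clip_zero = pmax(fcWindow, 0))
  diag(A) <- 0
  diag(A) <- 1                      # A~ = A + I
  d <- rowSums(A)
  if (any(d <= 0))
    stop("degree must be positive after self-loop augmentation")
  dr <- 1 / sqrt(d)
  symmetrize(A * outer(dr, dr))
}

#' Build the per-window graph sequence of one subject or a cohort
#'
#' Pairs the clustering-coefficient node features with the normalized
#' weighted adjacency of every window — the exact inputs of the dynamic
#' graph convolution. Apply the edge mask first ([applyEdgeMask()]).
#'
#' @param fc a masked [DynamicFC-class] or [DynamicFCSet-class].
#' @param negativePolicy see [normalizeAdjacency()].
#' @param eq3Literal see [localClustering()].
#' @return a [GraphSequence-class], or a list of them for a cohort.
#' @export
setGeneric("buildGraphSequence",
  function(fc, negativePolicy = "abs", eq3Literal = FALSE)
    standardGeneric("buildGraphSequence"))

#' @rdname buildGraphSequence
#' @export
setMethod("buildGraphSequence", "DynamicFC",
  function(fc, negativePolicy, eq3Literal) {
    new("GraphSequence", subjectId = fc@subjectId,
        nodeFeatures = nodeFeatureSequence(fc, eq3Literal = eq3Literal),
        normAdj = lapply(fc@matrices, normalizeAdjacency,
                         negativePolicy = negativePolicy))
  })

#' @rdname buildGraphSequence
#' @export
setMethod("buildGraphSequence", "DynamicFCSet",
  function(fc, negativePolicy, eq3Literal) {
    seqs <- lapply(fc@fc, buildGraphSequence,
                   negativePolicy = negativePolicy, eq3Literal = eq3Literal)
    names(seqs) <- subjectIds(fc)
    seqs
  })
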