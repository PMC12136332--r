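#' Create a synthetic cohort specification
#'
#' Defines a two-group cohort of ROI-level BOLD-like multivariate time
#' series. Each subject follows a latent Markov chain over `nStates`
#' correlation states; samples are drawn from the active state's zero-mean
#' multivariate normal with additive independent observation noise. The
#' eMCI group's state correlations on `effectEdges` are reduced by
#' `effectSize` relative to NC (hypoconnectivity), so the group difference
#' lives in the connectivity structure, not in signal amplitude.
#'
#' @param nRegions number of regions (default 116, the AAL atlas size).
#' @param nTimepoints retained series length (default 137: 140 acquired
#'   volumes minus the 3 discarded for magnetization equilibrium).
#' @param nPerGroup subjects per group (default 40).
#' @param effectEdges two-column matrix (or list of length-2 vectors) of
#'   1-based region index pairs carrying the group difference.
#' @param effectSize correlation reduction on effect edges, in [0, 1).
#' @param nStates latent covariance states (default 3).
#' @param switchProb per-step probability of switching state (default 0.05).
#' @param noiseSd observation noise standard deviation (default 0.2).
#' @param seed master seed; the cohort is a pure function of the
#'   specification object.
#' @return a [SimSpec-class] object.
#' @examples
#' sp <- simSpec(nRegions = 20, nPerGroup = 5,
#'               effectEdges = cbind(1:4, 2:5), effectSize = 0.4, seed = 1)
#' cohort <- makeCohort(sp)
#' @export
simSpec <- function(nRegions = 116L, nTimepoints = 137L, nPerGroup = 40L,
                    effectEdges = matrix(integer(0), ncol = 2),
                    effectSize = 0, nStates = 3L, switchProb = 0.05,
                    noiseSd = 0.2, seed = 1L) {
  if (is.list(effectEdges))
    effectEdges <- do.call(rbind, effectEdges)
  effectEdges <- matrix(as.integer(effectEdges), ncol = 2)
  new("SimSpec", nRegions = as.integer(nRegions),
      nTimepoints = as.integer(nTimepoints),
      nPerGroup = as.integer(nPerGroup), effectEdges = effectEdges,
      effectSize = as.numeric(effectSize), nStates = as.integer(nStates),
      switchProb = as.numeric(switchProb), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

#' Project a symmetric matrix to the nearest positive-definite matrix
#'
#' Eigenvalue clipping: eigenvalues below `floor` are raised to `floor` and
#' the matrix reassembled. Deterministic; for correlation-like input the
#' result is rescaled back to unit diagonal.
#'
#' @param m symmetric numeric matrix.
#' @param floor smallest admissible eigenvalue (default 1e-6).
#' @param corr rescale result to a correlation matrix (unit diagonal)?
#' @return symmetric positive-definite matrix.
#' @export
nearestPD <- function(m, floor = 1e-6, corr = TRUE) {
  stopifnot(isSymmetric(unname(m)))
  e <- eigen(m, symmetric = TRUE)
  lam <- pmax(e$values, floor)
  out <- e$vectors %*% (lam * t(e$vectors))
  out <- (out + t(out)) / 2
  if (corr) out <- stats::cov2cor(out)
  if (min(eigen(out, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("matrix is not positive definite after projection")
  out
}

## State correlation matrices shared by the whole cohort: a random sparse
## graph with positive weights, symmetrized and diagonally loaded, gives
## non-trivial triangle (clustering-coefficient) structure. Depends only on
## spec@seed, never on subject seeds.
stateCorrelations <- function(spec, group) {
  R <- spec@nRegions
  states <- withSeed(spec@seed + 104729L, {
    lapply(seq_len(spec@nStates), function(s) {
      G <- matrix(0, R, R)
      up <- upper.tri(G)
      present <- stats::runif(sum(up)) < 0.15
      w <- ifelse(present, stats::runif(sum(up), 0.2, 0.8), 0)
      G[up] <- w
      G <- G + t(G)
      lam <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
      diag(G) <- abs(min(lam)) + 0.5
      stats::cov2cor(G)
    })
  })
  if (group == "eMCI" && nrow(spec@effectEdges) > 0 && spec@effectSize > 0) {
    idx <- rbind(spec@effectEdges, spec@effectEdges[, 2:1, drop = FALSE])
    states <- lapply(states, function(C) {
      C[idx] <- pmax(C[idx] - spec@effectSize, -0.99)
      nearestPD(C)
    })
  }
  states
}

#' Simulate one subject's ROI time-series matrix
#'
#' Draws a latent state path from a Markov chain with switch probability
#' `spec@switchProb`, then samples each time point from the active state's
#' zero-mean multivariate normal (unit variances, shared state correlation
#' structure) and adds independent Gaussian observation noise. For group
#' `"eMCI"` the state correlations on `spec@effectEdges` are reduced by
#' `spec@effectSize`; shifted matrices are projected to the nearest
#' positive-definite correlation matrix by eigenvalue clipping before
#' sampling.
#'
#' @param spec a [SimSpec-class].
#' @param group `"NC"` or `"eMCI"`.
#' @param subjectSeed integer seed; the output is a pure function of
#'   `(spec, group, subjectSeed)`.
#' @return numeric `nRegions` x `nTimepoints` matrix.
#' @export
simulateSubject <- function(spec, group = c("NC", "eMCI"),
                            subjectSeed = 1L) {
  group <- match.arg(group)
  validObject(spec)
  R <- spec@nRegions; M <- spec@nTimepoints
  states <- stateCorrelations(spec, group)
  chols <- lapply(states, function(C) chol(C))
  withSeed(as.integer(subjectSeed), {
    z <- integer(M)
    z[1] <- sample.int(spec@nStates, 1L)
    if (M > 1) for (t in 2:M) {
      z[t] <- if (stats::runif(1) < spec@switchProb)
        sample.int(spec@nStates, 1L) else z[t - 1]
    }
    E <- matrix(stats::rnorm(R * M), R, M)
    Y <- matrix(0, R, M)
    for (s in unique(z)) {
      cols <- which(z == s)
      Y[, cols] <- crossprod(chols[[s]], E[, cols, drop = FALSE])
    }
    if (spec@noiseSd > 0)
      Y <- Y + matrix(stats::rnorm(R * M, sd = spec@noiseSd), R, M)
    Y
  })
}

#' Generate a full two-group synthetic cohort
#'
#' Produces `nPerGroup` NC and `nPerGroup` eMCI subjects with subject seeds
#' derived deterministically from `spec@seed`, so the cohort is a pure
#' function of the specification.
#'
#' @param spec a [SimSpec-class].
#' @return a [RoiTimeSeriesSet-class] of `2 * nPerGroup` subjects.
#' @export
makeCohort <- function(spec) {
  validObject(spec)
  groups <- rep(GROUP_LEVELS, each = spec@nPerGroup)
  n <- length(groups)
  ids <- sprintf("%s_%03d", groups, unlist(lapply(GROUP_LEVELS, function(g)
    seq_len(spec@nPerGroup))))
  seeds <- (spec@seed %% 100000L) * 10000L + seq_len(n)
  series <- lapply(seq_len(n), function(i)
    simulateSubject(spec, groups[i], seeds[i]))
  names(series) <- ids
  new("RoiTimeSeriesSet", series = series,
      labels = factor(groups, levels = GROUP_LEVELS), subjectIds = ids)
}
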