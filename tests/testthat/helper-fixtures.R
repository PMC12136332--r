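# Shared fixture builders; everything is generated in code under fixed
# seeds, nothing is read from disk.

# Small two-group cohort with the planted effect confined to the first
# `effectNodes` regions (dense within-block edge set).
fixtureSpec <- function(nRegions = 12, nPerGroup = 6, nTimepoints = 60,
                        effectNodes = 4, effectSize = 0.5, seed = 7,
                        ...) {
  edges <- t(utils::combn(effectNodes, 2))
  simSpec(nRegions = nRegions, nTimepoints = nTimepoints,
          nPerGroup = nPerGroup, effectEdges = edges,
          effectSize = effectSize, seed = seed, ...)
}

# Random symmetric matrix with unit diagonal and entries in [-1, 1].
randomFCMatrix <- function(R) {
  m <- matrix(stats::runif(R * R, -1, 1), R, R)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# A DynamicFC with random (valid) window matrices.
randomDynamicFC <- function(R = 6, K = 3, id = "s1", order = "low") {
  new("DynamicFC", subjectId = id, order = order,
      matrices = replicate(K, randomFCMatrix(R), simplify = FALSE))
}

# A DynamicFCSet whose per-subject matrices are pure noise (null cohort in
# FC space, bypassing time-series simulation for speed).
randomFCSet <- function(nPerGroup = 5, R = 6, K = 3) {
  fc <- lapply(seq_len(2 * nPerGroup), function(i)
    randomDynamicFC(R, K, id = sprintf("s%02d", i)))
  new("DynamicFCSet", fc = fc,
      labels = factor(rep(c("NC", "eMCI"), each = nPerGroup),
                      levels = c("NC", "eMCI")))
}

# Independent brute-force oracle for the triangle-intensity weighted
# clustering coefficient: explicit loop over neighbour pairs.
clusteringOracle <- function(W) {
  R <- nrow(W)
  mx <- max(W)
  Wn <- if (mx > 0) W / mx else W
  out <- numeric(R)
  for (i in seq_len(R)) {
    nb <- which(Wn[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    acc <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      j <- nb[a]; h <- nb[b]
      if (Wn[j, h] != 0)
        acc <- acc + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
    }
    out[i] <- 2 * acc / (k * (k - 1))
  }
  out
}

# Graph sequences + labels for a tiny trained-model fixture.
tinyGraphData <- function(spec = fixtureSpec(), L = 20, s = 10,
                          pThreshold = 0.5) {
  cohort <- makeCohort(spec)
  fc <- buildLowOrder(cohort, L = L, s = s)
  mask <- fitEdgeMask(fc, pThreshold = pThreshold)
  masked <- applyEdgeMask(fc, mask)
  list(seqs = buildGraphSequence(masked), labels = groupLabels(cohort),
       masked = masked, mask = mask, fc = fc, cohort = cohort)
}
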