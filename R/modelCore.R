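## ---- elementary blocks (exported, oracle-testable) ----------------------

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

#' One graph-convolution layer
#'
#' Propagation rule of a graph convolutional layer with a weighted
#' adjacency: `relu(normAdj %*% H %*% W)`, where `normAdj` is the
#' symmetrically normalized self-loop augmented FC matrix of one window
#' (see [normalizeAdjacency()]) and `H` holds one feature column per node.
#'
#' @param H R x d node feature matrix.
#' @param normAdjMat R x R normalized adjacency.
#' @param W d x d' weight matrix.
#' @return R x d' matrix.
#' @export
gcnLayerForward <- function(H, normAdjMat, W) {
  if (!is.matrix(H)) H <- matrix(H, ncol = 1)
  if (nrow(normAdjMat) != ncol(normAdjMat) || ncol(normAdjMat) != nrow(H) ||
      ncol(H) != nrow(W))
    stop(sprintf("non-conformable shapes: adj %dx%d, H %dx%d, W %dx%d",
                 nrow(normAdjMat), ncol(normAdjMat), nrow(H), ncol(H),
                 nrow(W), ncol(W)))
  relu(normAdjMat %*% H %*% W)
}

#' One LSTM cell step
#'
#' Standard LSTM recurrence on the concatenated vector `[hPrev, x]`:
#' forget gate `f = sigmoid(Wf [hPrev, x] + bf)`, input gate
#' `i = sigmoid(Wi [hPrev, x] + bi)`, candidate
#' `Ctilde = tanh(Wc [hPrev, x] + bc)`, cell `C = f * CPrev + i * Ctilde`,
#' output gate `o = sigmoid(Wo [hPrev, x] + bo)` and hidden state
#' `h = o * tanh(C)`.
#'
#' @param hPrev previous hidden state (length H).
#' @param cPrev previous cell state (length H).
#' @param x current input (length d).
#' @param params list with gate weight matrices `Wf`, `Wi`, `Wc`, `Wo`
#'   (each H x (H + d), acting on `c(hPrev, x)`) and bias vectors `bf`,
#'   `bi`, `bc`, `bo` (length H).
#' @return list with `h`, `C` and the gate activations `f`, `i`, `o`,
#'   `Ctilde`.
#' @export
lstmCellForward <- function(hPrev, cPrev, x, params) {
  z <- c(hPrev, x)
  if (ncol(params$Wf) != length(z))
    stop(sprintf("gate weights expect input of length %d, got %d",
                 ncol(params$Wf), length(z)))
  f <- sigmoid(as.numeric(params$Wf %*% z) + params$bf)
  i <- sigmoid(as.numeric(params$Wi %*% z) + params$bi)
  Ctilde <- tanh(as.numeric(params$Wc %*% z) + params$bc)
  C <- f * cPrev + i * Ctilde
  o <- sigmoid(as.numeric(params$Wo %*% z) + params$bo)
  h <- o * tanh(C)
  list(h = h, C = C, f = f, i = i, o = o, Ctilde = Ctilde)
}

## ---- parameters ----------------------------------------------------------

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

## Gate column blocks in the fused LSTM weight matrix: [f | i | g | o].
gateIdx <- function(H) list(f = 1:H, i = H + 1:H, g = 2 * H + 1:H,
                            o = 3 * H + 1:H)

## Initialize all learnable parameters; consumes the active RNG stream.
## GCN weights start nonnegative (|Glorot|): node features and normalized
## adjacencies are nonnegative, so with zero-mean weights the narrow
## (width-1) ReLU output unit is dead at initialization for many seeds —
## every pre-activation <= 0, no gradient ever reaches the GCN. Nonnegative
## weights guarantee a live signal path. Forget-gate biases start at 1 so
## early training does not flush the cell state.
initParams <- function(config, R) {
  widths <- config$gcnWidths
  gcn <- lapply(seq_len(length(widths) - 1), function(l)
    abs(glorot(widths[l], widths[l + 1])))
  H <- config$lstmHidden
  lstm <- lapply(seq_len(config$lstmLayers), function(l) {
    din <- if (l == 1) R else H
    W <- glorot(H + din, 4 * H)
    b <- numeric(4 * H)
    b[gateIdx(H)$f] <- 1
    list(W = W, b = b)
  })
  head <- list(W = glorot(H, 2), b = numeric(2))
  list(gcn = gcn, lstm = lstm, head = head)
}

packParams <- function(p) {
  unlist(c(lapply(p$gcn, as.numeric),
           lapply(p$lstm, function(l) c(as.numeric(l$W), l$b)),
           list(as.numeric(p$head$W), p$head$b)))
}

unpackParams <- function(v, skeleton) {
  pos <- 0L
  take <- function(n) {
    out <- v[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  gcn <- lapply(skeleton$gcn, function(W)
    matrix(take(length(W)), nrow(W), ncol(W)))
  lstm <- lapply(skeleton$lstm, function(l)
    list(W = matrix(take(length(l$W)), nrow(l$W), ncol(l$W)),
         b = take(length(l$b))))
  head <- list(W = matrix(take(length(skeleton$head$W)), nrow(skeleton$head$W),
                          ncol(skeleton$head$W)),
               b = take(length(skeleton$head$b)))
  stopifnot(pos == length(v))
  list(gcn = gcn, lstm = lstm, head = head)
}

zeroLike <- function(p) unpackParams(numeric(length(packParams(p))), p)

## ---- data preparation ----------------------------------------------------

## Per subject: sparse block-diagonal of the K normalized adjacencies
## (KR x KR), the stacked feature column (window blocks of R rows) and the
## precomputed product bd %*% f used by the first GCN layer. The sparse
## matrix is assembled directly from per-window triplets (column-sorted by
## construction), and the raw triplets are kept so batches can be fused
## without re-sorting.
prepGraphData <- function(seqs) {
  lapply(seqs, function(gs) {
    stopifnot(is(gs, "GraphSequence"))
    K <- nWindows(gs); R <- nRegions(gs)
    KR <- K * R
    trips <- lapply(seq_len(K), function(k) {
      m <- gs@normAdj[[k]]
      nz <- which(m != 0)                    # column-major, hence sorted
      off <- (k - 1L) * R
      list(i = ((nz - 1L) %% R) + off,       # 0-based rows
           j = ((nz - 1L) %/% R) + 1L + off, # 1-based cols
           x = m[nz])
    })
    i0 <- as.integer(unlist(lapply(trips, `[[`, "i"), use.names = FALSE))
    j1 <- as.integer(unlist(lapply(trips, `[[`, "j"), use.names = FALSE))
    x <- as.numeric(unlist(lapply(trips, `[[`, "x"), use.names = FALSE))
    counts <- tabulate(j1, KR)
    bd <- methods::new("dgCMatrix", i = i0,
                       p = as.integer(c(0L, cumsum(counts))), x = x,
                       Dim = c(KR, KR))
    f <- matrix(as.numeric(t(gs@nodeFeatures)), ncol = 1)
    list(bd = bd, i0 = i0, counts = counts, x = x, f = f,
         bdf = as.matrix(bd %*% f), K = K, R = R)
  })
}

## ---- fused forward / backward over a batch -------------------------------

## Fuse a batch of prepared subjects into one block-diagonal sparse
## adjacency (B*K*R square) plus the stacked feature column, so every GCN
## layer is a single sparse-dense product for the whole batch.
assembleBatch <- function(batch) {
  K <- unique(vapply(batch, function(s) s$K, integer(1)))
  if (length(K) != 1)
    stop("all subjects in a batch must share the window count K")
  R <- batch[[1]]$R
  B <- length(batch)
  bd <- if (B == 1) batch[[1]]$bd else {
    KR <- K * R
    offs <- (seq_len(B) - 1L) * KR
    i0 <- unlist(lapply(seq_len(B), function(b) batch[[b]]$i0 + offs[b]),
                 use.names = FALSE)
    counts <- unlist(lapply(batch, `[[`, "counts"), use.names = FALSE)
    methods::new("dgCMatrix", i = as.integer(i0),
                 p = as.integer(c(0L, cumsum(counts))),
                 x = as.numeric(unlist(lapply(batch, `[[`, "x"),
                                            use.names = FALSE)),
                 Dim = c(B * KR, B * KR))
  }
  f <- do.call(rbind, lapply(batch, function(s) s$f))
  bdf <- do.call(rbind, lapply(batch, function(s) s$bdf))
  list(bd = bd, f = f, bdf = bdf, K = K, R = R, B = B)
}

## GCN forward on an assembled batch; weights are shared across windows
## (and trivially across subjects). Returns caches for backprop.
gcnForwardBatch <- function(ab, gcnW) {
  L <- length(gcnW)
  P <- vector("list", L); Z <- vector("list", L); A <- vector("list", L + 1)
  A[[1]] <- ab$f
  for (l in seq_len(L)) {
    P[[l]] <- if (l == 1) ab$bdf else as.matrix(ab$bd %*% A[[l]])
    Z[[l]] <- P[[l]] %*% gcnW[[l]]
    A[[l + 1]] <- relu(Z[[l]])
  }
  list(out = A[[L + 1]], P = P, Z = Z)
}

gcnBackwardBatch <- function(ab, gcnW, cache, dOut) {
  L <- length(gcnW)
  dA <- dOut
  g <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dZ <- dA * (cache$Z[[l]] > 0)
    g[[l]] <- crossprod(cache$P[[l]], dZ)
    if (l > 1) {
      dP <- dZ %*% t(gcnW[[l]])
      dA <- as.matrix(ab$bd %*% dP)   # bd symmetric
    }
  }
  g
}

## Inverted-dropout masks for every LSTM layer output that is fed upward:
## full B x H x K cubes for the layers below the top, a single B x H mask
## for the top layer's final hidden state (all the head consumes). Drawn
## from the active RNG stream, pre-scaled by 1/(1-p).
drawDropMasks <- function(config, B, K) {
  p <- config$dropout
  H <- config$lstmHidden
  nL <- config$lstmLayers
  masks <- vector("list", nL)
  if (nL > 1)
    for (l in seq_len(nL - 1))
      masks[[l]] <- array((stats::runif(B * H * K) >= p) / (1 - p),
                          c(B, H, K))
  masks[[nL]] <- matrix((stats::runif(B * H) >= p) / (1 - p), B, H)
  masks
}

## Full forward pass (and optional backward pass) over a batch of prepared
## subjects: R-side sparse GCN feeding the compiled fused LSTM + softmax
## head kernel. When `train` is TRUE, inverted dropout is applied to every
## LSTM layer output fed upward; masks are drawn from the active RNG
## stream. The loss is cross-entropy plus an L2 penalty on all weight
## matrices; it and the returned gradients are pure functions of the
## parameters (given fixed masks).
engineForward <- function(params, batch, config, y = NULL, train = FALSE,
                          wantGrad = FALSE) {
  ab <- assembleBatch(batch)
  B <- ab$B; K <- ab$K; R <- ab$R

  gcnCache <- gcnForwardBatch(ab, params$gcn)
  ## stacked B*K*R column (region fastest, then window, then subject)
  ## -> B x R x K input cube
  X <- aperm(array(gcnCache$out, c(R, K, B)), c(3, 1, 2))

  masks <- if (train && config$dropout > 0) drawDropMasks(config, B, K)
    else list()
  yv <- if (is.null(y)) integer(0) else as.integer(y)
  cpp <- .lstmHeadFused(X, lapply(params$lstm, `[[`, "W"),
                        lapply(params$lstm, `[[`, "b"),
                        params$head$W, params$head$b, yv, masks,
                        config$l2, wantGrad)

  loss <- NULL
  if (!is.null(y)) {
    l2term <- config$l2 / 2 *
      (sum(vapply(params$gcn, function(W) sum(W^2), numeric(1))) +
       sum(vapply(params$lstm, function(l) sum(l$W^2), numeric(1))) +
       sum(params$head$W^2))
    loss <- cpp$ce + l2term
  }
  out <- list(loss = loss, probs = cpp$probs, B = B, K = K, R = R)

  if (wantGrad) {
    grads <- list(
      gcn = NULL,
      lstm = lapply(seq_len(config$lstmLayers), function(l)
        list(W = cpp$gradLstmW[[l]], b = as.numeric(cpp$gradLstmB[[l]]))),
      head = list(W = cpp$gradHeadW, b = as.numeric(cpp$gradHeadB)))
    ## dX cube (B x R x K) -> stacked column matching the GCN output layout
    dStack <- matrix(as.numeric(aperm(cpp$dX, c(2, 3, 1))), ncol = 1)
    g <- gcnBackwardBatch(ab, params$gcn, gcnCache, dStack)
    grads$gcn <- lapply(seq_along(g), function(l)
      g[[l]] + config$l2 * params$gcn[[l]])
    out$grads <- grads
  }
  out
}

## Loss (and optionally gradients) as a pure function of the parameters;
## used by the training loop and by finite-difference gradient checks.
modelLossGrad <- function(params, batch, y, config, train = FALSE,
                          wantGrad = TRUE) {
  engineForward(params, batch, config, y = y, train = train,
                wantGrad = wantGrad)
}
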