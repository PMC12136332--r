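test_that("a GCN layer equals its loop-based arithmetic oracle", {
  set.seed(31)
  # trivial cases
  H <- matrix(abs(rnorm(12)), 4, 3)
  expect_equal(gcnLayerForward(H, diag(4), diag(3)), H)
  expect_equal(gcnLayerForward(matrix(0, 4, 3), randomFCMatrix(4),
                               matrix(rnorm(6), 3, 2)),
               matrix(0, 4, 2))
  # random shapes vs explicit triple-loop evaluation
  for (r in 1:100) {
    R <- sample(3:6, 1); d <- sample(1:3, 1); d2 <- sample(1:3, 1)
    A <- matrix(rnorm(R * R), R); A <- (A + t(A)) / 2
    Hm <- matrix(rnorm(R * d), R, d)
    W <- matrix(rnorm(d * d2), d, d2)
    oracle <- matrix(0, R, d2)
    for (i in seq_len(R)) for (j in seq_len(d2)) {
      acc <- 0
      for (u in seq_len(R)) for (v in seq_len(d))
        acc <- acc + A[i, u] * Hm[u, v] * W[v, j]
      oracle[i, j] <- max(acc, 0)
    }
    expect_equal(unname(gcnLayerForward(Hm, A, W)), oracle,
                 tolerance = 1e-9)
  }
  expect_error(gcnLayerForward(matrix(0, 3, 2), diag(4), diag(2)),
               "non-conformable")
})

test_that("the LSTM cell reproduces its defining equations", {
  H <- 4; d <- 3
  zeroP <- list(Wf = matrix(0, H, H + d), Wi = matrix(0, H, H + d),
                Wc = matrix(0, H, H + d), Wo = matrix(0, H, H + d),
                bf = numeric(H), bi = numeric(H), bc = numeric(H),
                bo = numeric(H))
  out <- lstmCellForward(numeric(H), numeric(H), numeric(d), zeroP)
  expect_equal(out$f, rep(0.5, H))
  expect_equal(out$i, rep(0.5, H))
  expect_equal(out$o, rep(0.5, H))
  expect_equal(out$Ctilde, numeric(H))
  expect_equal(out$C, numeric(H))
  expect_equal(out$h, numeric(H))

  # saturated forget gate passes the previous cell state through
  set.seed(32)
  p <- lapply(zeroP, function(z) if (is.matrix(z))
    matrix(rnorm(length(z), sd = 0.3), nrow(z)) else rnorm(length(z), sd = 0.3))
  names(p) <- names(zeroP)
  cPrev <- rnorm(H); hPrev <- rnorm(H); x <- rnorm(d)
  pSat <- p; pSat$bf <- rep(20, H)
  o <- lstmCellForward(hPrev, cPrev, x, pSat)
  expect_equal(o$C, cPrev + o$i * o$Ctilde, tolerance = 1e-8)

  # random parameters vs independent step-by-step evaluation
  for (r in 1:100) {
    p <- list(Wf = matrix(rnorm(H * (H + d)), H), Wi = matrix(rnorm(H * (H + d)), H),
              Wc = matrix(rnorm(H * (H + d)), H), Wo = matrix(rnorm(H * (H + d)), H),
              bf = rnorm(H), bi = rnorm(H), bc = rnorm(H), bo = rnorm(H))
    hPrev <- rnorm(H); cPrev <- rnorm(H); x <- rnorm(d)
    got <- lstmCellForward(hPrev, cPrev, x, p)
    z <- c(hPrev, x)
    sig <- function(v) 1 / (1 + exp(-v))
    f <- sig(drop(p$Wf %*% z) + p$bf)
    i <- sig(drop(p$Wi %*% z) + p$bi)
    g <- tanh(drop(p$Wc %*% z) + p$bc)
    C <- f * cPrev + i * g
    o2 <- sig(drop(p$Wo %*% z) + p$bo)
    expect_equal(got$C, C, tolerance = 1e-12)
    expect_equal(got$h, o2 * tanh(C), tolerance = 1e-12)
    expect_true(all(got$f > 0 & got$f < 1))
    expect_true(all(abs(got$Ctilde) < 1))
  }
})

test_that("the fused engine equals the composition of the elementary blocks", {
  set.seed(33)
  d <- tinyGraphData()
  seqs <- d$seqs[1:3]
  cfg <- trainConfig(gcnHidden = 5, lstmHidden = 6, lstmLayers = 2,
                     dropout = 0, seed = 2)
  prep <- dwgnn:::prepGraphData(seqs)
  params <- withr::with_seed(99, dwgnn:::initParams(cfg, prep[[1]]$R))
  fw <- dwgnn:::engineForward(params, prep, cfg)

  # independent composition: per-window GCN via gcnLayerForward, then a
  # manual per-layer loop over lstmCellForward, then the linear head
  H <- cfg$lstmHidden
  sliceGate <- function(W, b, gate) {
    idx <- dwgnn:::gateIdx(H)[[gate]]
    list(W = t(W[, idx, drop = FALSE]), b = b[idx])
  }
  for (sj in seq_along(seqs)) {
    gs <- seqs[[sj]]
    K <- nWindows(gs)
    X <- matrix(0, K, nRegions(gs))
    for (k in seq_len(K)) {
      h0 <- matrix(nodeFeatures(gs)[k, ], ncol = 1)
      h1 <- gcnLayerForward(h0, normAdj(gs)[[k]], params$gcn[[1]])
      X[k, ] <- gcnLayerForward(h1, normAdj(gs)[[k]], params$gcn[[2]])
    }
    inp <- X
    for (l in seq_len(cfg$lstmLayers)) {
      Wl <- params$lstm[[l]]$W; bl <- params$lstm[[l]]$b
      cell <- list(
        Wf = sliceGate(Wl, bl, "f")$W, bf = sliceGate(Wl, bl, "f")$b,
        Wi = sliceGate(Wl, bl, "i")$W, bi = sliceGate(Wl, bl, "i")$b,
        Wc = sliceGate(Wl, bl, "g")$W, bc = sliceGate(Wl, bl, "g")$b,
        Wo = sliceGate(Wl, bl, "o")$W, bo = sliceGate(Wl, bl, "o")$b)
      h <- numeric(H); cc <- numeric(H)
      outSeq <- matrix(0, K, H)
      for (k in seq_len(K)) {
        st <- lstmCellForward(h, cc, inp[k, ], cell)
        h <- st$h; cc <- st$C
        outSeq[k, ] <- h
      }
      inp <- outSeq
    }
    logits <- drop(inp[K, ] %*% params$head$W) + params$head$b
    probs <- exp(logits - max(logits))
    probs <- probs / sum(probs)
    expect_equal(unname(fw$probs[sj, ]), unname(probs), tolerance = 1e-9)
  }
})

test_that("inference is deterministic and sensitive to window order", {
  set.seed(34)
  d <- tinyGraphData()
  cfg <- trainConfig(gcnHidden = 4, lstmHidden = 6, lstmLayers = 2,
                     dropout = 0, seed = 3)
  prep <- dwgnn:::prepGraphData(d$seqs[c(1, 1)])   # same subject twice
  params <- withr::with_seed(7, dwgnn:::initParams(cfg, prep[[1]]$R))
  fw <- dwgnn:::engineForward(params, prep, cfg)
  expect_identical(fw$probs[1, ], fw$probs[2, ])

  gs <- d$seqs[[2]]
  K <- nWindows(gs)
  rev <- new("GraphSequence", subjectId = "rev",
             nodeFeatures = nodeFeatures(gs)[K:1, , drop = FALSE],
             normAdj = normAdj(gs)[K:1])
  prep2 <- dwgnn:::prepGraphData(list(gs, rev))
  fw2 <- dwgnn:::engineForward(params, prep2, cfg)
  expect_false(isTRUE(all.equal(fw2$probs[1, ], fw2$probs[2, ])))
})

test_that("analytic gradients match finite differences on a tiny model", {
  set.seed(35)
  d <- tinyGraphData(fixtureSpec(nRegions = 6, nPerGroup = 2,
                                 nTimepoints = 40, effectNodes = 3,
                                 seed = 12), L = 20, s = 10)
  cfg <- trainConfig(gcnHidden = 3, lstmHidden = 5, lstmLayers = 3,
                     dropout = 0, l2 = 1e-3, seed = 4)
  err <- gradientCheck(d$seqs, d$labels, cfg, nCheck = 120, seed = 6)
  expect_lt(err, 1e-4)
})

test_that("training reduces the loss and is reproducible under a fixed seed", {
  sp <- fixtureSpec(nRegions = 10, nPerGroup = 10, nTimepoints = 80,
                    effectNodes = 5, effectSize = 0.6, seed = 41)
  d <- tinyGraphData(sp, L = 30, s = 10, pThreshold = 0.05)
  # dropout off: the descent check targets the optimizer, not the
  # regularization noise
  cfg <- trainConfig(epochs = 25, patience = 25, gcnHidden = 8,
                     lstmHidden = 16, lstmLayers = 2, batchSize = 16,
                     dropout = 0, seed = 5)
  m1 <- trainModel(d$seqs, d$labels, cfg)
  m2 <- trainModel(d$seqs, d$labels, cfg)
  expect_identical(m1@history, m2@history)          # bit-identical trajectory
  expect_identical(m1@params, m2@params)
  h <- m1@history
  expect_lt(mean(tail(h$trainLoss, 5)), mean(head(h$trainLoss, 3)))
  # prediction plumbing
  pr <- predictModel(m1, d$seqs[1:3])
  expect_equal(nrow(pr), 3)
  expect_equal(pr$probNC + pr$probEMCI, rep(1, 3), tolerance = 1e-9)
})

test_that("degenerate training inputs are rejected", {
  d <- tinyGraphData()
  cfg <- trainConfig(seed = 1)
  oneClass <- factor(rep("NC", length(d$seqs)), levels = c("NC", "eMCI"))
  expect_error(trainModel(d$seqs, oneClass, cfg), "both classes|degenerate")
  expect_error(trainModel(d$seqs, d$labels, cfg,
                          split = list(train = integer(0), val = 1:2,
                                       test = 3:4)),
               "degenerate")
})
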