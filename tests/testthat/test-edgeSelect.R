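test_that("per-edge t-tests agree with stats::t.test on every edge", {
  set.seed(11)
  fcset <- randomFCSet(nPerGroup = 6, R = 5, K = 4)
  mask <- fitEdgeMask(fcset, pThreshold = 0.05)
  maskW <- fitEdgeMask(fcset, pThreshold = 0.05, welch = TRUE)
  es <- dwgnn:::subjectEdgeStats(fcset)
  grp <- groupLabels(fcset)
  up <- which(upper.tri(matrix(0, 5, 5)), arr.ind = TRUE)
  for (e in seq_len(nrow(up))) {
    vals <- es$stats[, e]
    pS <- stats::t.test(vals[grp == "NC"], vals[grp == "eMCI"],
                        var.equal = TRUE)$p.value
    pW <- stats::t.test(vals[grp == "NC"], vals[grp == "eMCI"])$p.value
    expect_equal(maskPValues(mask)[up[e, 1], up[e, 2]], pS,
                 tolerance = 1e-12)
    expect_equal(maskPValues(maskW)[up[e, 1], up[e, 2]], pW,
                 tolerance = 1e-12)
  }
})

test_that("identical groups give p = 1 everywhere and an empty mask", {
  # two subjects per group with the same pair of FC profiles in each group:
  # equal group means, equal variances, t = 0
  a <- randomDynamicFC(4, 2, "a"); b <- randomDynamicFC(4, 2, "b")
  cloneAs <- function(f, id) new("DynamicFC", subjectId = id,
                                 order = f@order, matrices = f@matrices)
  fcset <- new("DynamicFCSet",
               fc = list(a, b, cloneAs(a, "c"), cloneAs(b, "d")),
               labels = factor(c("NC", "NC", "eMCI", "eMCI"),
                               levels = c("NC", "eMCI")))
  mask <- fitEdgeMask(fcset)
  off <- upper.tri(maskKeep(mask))
  expect_true(all(maskPValues(mask)[off] == 1))
  expect_false(any(maskKeep(mask)[off]))
  expect_true(all(diag(maskKeep(mask))))  # diagonal kept by convention
})

test_that("null p-values are approximately uniform", {
  set.seed(12)
  ps <- c()
  for (r in 1:8) {
    fcset <- randomFCSet(nPerGroup = 10, R = 8, K = 2)
    mask <- fitEdgeMask(fcset)
    ps <- c(ps, maskPValues(mask)[upper.tri(maskKeep(mask))])
  }
  frac <- mean(ps < 0.05)
  n <- length(ps)                               # 224 null edges
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 1e-9)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("planted effect edges are recovered above the background rate", {
  hits <- c(); bg <- c()
  for (seed in 1:3) {
    sp <- fixtureSpec(nRegions = 12, nPerGroup = 15, nTimepoints = 100,
                      effectNodes = 5, effectSize = 0.5, seed = 30 + seed)
    co <- makeCohort(sp)
    fc <- buildLowOrder(co, L = 30, s = 10)
    mask <- fitEdgeMask(fc)
    keep <- maskKeep(mask)
    eff <- sp@effectEdges
    isEff <- matrix(FALSE, 12, 12)
    isEff[eff] <- TRUE; isEff <- isEff | t(isEff)
    up <- upper.tri(keep)
    hits <- c(hits, mean(keep[up & isEff]))
    bg <- c(bg, mean(keep[up & !isEff]))
  }
  expect_gt(mean(hits), mean(bg))
  expect_gt(mean(hits), 0.5)
})

test_that("masking zeroes exactly the removed edges in every window", {
  set.seed(13)
  fc <- randomDynamicFC(6, 3)
  R <- 6
  # all-true mask: identity transformation
  allKeep <- matrix(TRUE, R, R)
  pv <- matrix(0.01, R, R); diag(pv) <- NA
  mAll <- new("EdgeMask", keep = allKeep, pValues = pv, pThreshold = 0.05,
              fittedOn = "x", order = "low")
  expect_equal(fcMatrices(applyEdgeMask(fc, mAll)), fcMatrices(fc))
  # all-false off-diagonal
  noKeep <- diag(R) == 1
  pv9 <- matrix(0.9, R, R); diag(pv9) <- NA
  mNone <- new("EdgeMask", keep = noKeep, pValues = pv9,
               pThreshold = 0.05, fittedOn = "x", order = "low")
  out <- applyEdgeMask(fc, mNone)
  for (m in fcMatrices(out)) {
    expect_true(all(m[upper.tri(m)] == 0))
    expect_equal(diag(m), diag(fcMatrices(fc)[[1]]))
  }
  # random mask: nonzero pattern = mask AND input pattern
  keep <- matrix(sample(c(TRUE, FALSE), R * R, replace = TRUE), R, R)
  keep <- keep & t(keep); diag(keep) <- TRUE
  mRnd <- new("EdgeMask", keep = keep, pValues = mNone@pValues,
              pThreshold = 0.05, fittedOn = "x", order = "low")
  outR <- applyEdgeMask(fc, mRnd)
  for (k in 1:3) {
    inM <- fcMatrices(fc)[[k]]; o <- fcMatrices(outR)[[k]]
    expect_equal(o != 0, (inM != 0) & keep)
    expect_true(isSymmetric(o))
  }
  expect_error(applyEdgeMask(randomDynamicFC(4, 2), mRnd), "mismatch")
})

test_that("raising the threshold never removes edges (monotonicity)", {
  set.seed(14)
  fcset <- randomFCSet(nPerGroup = 6, R = 7, K = 3)
  m1 <- fitEdgeMask(fcset, pThreshold = 0.05)
  m2 <- fitEdgeMask(fcset, pThreshold = 0.30)
  expect_true(all(maskKeep(m2)[maskKeep(m1)]))
})

test_that("mask fitting never sees test subjects (leakage safety)", {
  set.seed(15)
  fcset <- randomFCSet(nPerGroup = 8, R = 6, K = 3)
  trainIdx <- c(1:5, 9:13)
  mTrain <- fitEdgeMask(dwgnn:::subsetFCSet(fcset, trainIdx))
  # adding unseen test subjects to the cohort changes nothing
  mAgain <- fitEdgeMask(dwgnn:::subsetFCSet(fcset, trainIdx))
  expect_identical(maskPValues(mTrain), maskPValues(mAgain))
  expect_identical(mTrain@fittedOn, subjectIds(fcset)[trainIdx])
  expect_error(fitEdgeMask(dwgnn:::subsetFCSet(fcset, c(1, 9))),
               ">= 2 training subjects")
})

test_that("edge masks round-trip through their on-disk form bit-exactly", {
  set.seed(16)
  fcset <- randomFCSet(nPerGroup = 5, R = 6, K = 2)
  mask <- fitEdgeMask(fcset, pThreshold = 0.1)
  path <- file.path(tempdir(), "mask_test")
  writeEdgeMask(mask, path)
  back <- readEdgeMask(path)
  expect_identical(maskKeep(back), maskKeep(mask))
  expect_equal(maskPValues(back), maskPValues(mask), tolerance = 0)
  expect_identical(back@fittedOn, mask@fittedOn)
  expect_identical(back@pThreshold, mask@pThreshold)
})
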