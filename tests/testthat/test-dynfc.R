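test_that("window counts match brute-force enumeration", {
  # closed form vs explicit enumeration of admissible window starts
  bruteK <- function(M, L, s) length(seq(1, M - L + 1, by = s))
  expect_equal(windowCount(137, 30, 2), 54L)
  expect_equal(windowCount(30, 30, 5), 1L)
  set.seed(3)
  for (i in 1:50) {
    M <- sample(5:200, 1)
    L <- sample(2:M, 1)
    s <- sample(1:10, 1)
    expect_equal(windowCount(M, L, s), bruteK(M, L, s),
                 info = sprintf("M=%d L=%d s=%d", M, L, s))
  }
})

test_that("sliding windows cover the expected segments and drop the tail", {
  x <- matrix(seq_len(2 * 10), nrow = 2)   # M = 10
  segs <- slideWindows(x, L = 4, s = 3)
  expect_length(segs, 3)
  starts <- c(1, 4, 7)
  for (k in 1:3)
    expect_identical(segs[[k]], x[, starts[k]:(starts[k] + 3)])
  full <- slideWindows(x, L = 10, s = 2)
  expect_length(full, 1)
  expect_identical(full[[1]], x)
  expect_error(slideWindows(x, L = 11), "L=11 exceeds series length M=10")
})

test_that("discarding initial volumes keeps the remaining series intact", {
  x <- matrix(rnorm(3 * 140), nrow = 3)
  y <- discardInitialVolumes(x, 3)
  expect_equal(ncol(y), 137)
  expect_identical(y, x[, 4:140])
  expect_equal(length(slideWindows(y, 30, 2)), 54)
})

test_that("windowed correlation matches hand-computed and library values", {
  expect_equal(lowOrderFC(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  x <- rnorm(30)
  expect_equal(lowOrderFC(x, x), 1)
  expect_equal(lowOrderFC(x, -x), -1)
  set.seed(4)
  for (i in 1:100) {
    a <- rnorm(12); b <- rnorm(12)
    expect_equal(lowOrderFC(a, b), cor(a, b), tolerance = 1e-12)
  }
  expect_error(lowOrderFC(1:4, 1:5), "lengths differ")
  expect_warning(v <- lowOrderFC(rep(1, 5), rnorm(5)), "degenerate")
  expect_equal(v, 0)
})

test_that("low-order networks equal element-wise application of the pair correlation", {
  set.seed(5)
  x <- matrix(rnorm(6 * 40), 6)
  fc <- buildLowOrder(x, L = 15, s = 5, subjectId = "t")
  segs <- slideWindows(x, 15, 5)
  for (k in seq_along(segs)) {
    m <- fcMatrices(fc)[[k]]
    expect_true(isSymmetric(m))
    expect_equal(diag(m), rep(1, 6))
    expect_true(all(abs(m) <= 1 + 1e-9))
    for (i in 1:6) for (j in 1:6)
      expect_equal(m[i, j], lowOrderFC(segs[[k]][i, ], segs[[k]][j, ]),
                   tolerance = 1e-12)
  }
})

test_that("degenerate low-order cases behave as documented", {
  sig <- rnorm(40)
  same <- matrix(rep(sig, 4), nrow = 4, byrow = TRUE)
  fc <- buildLowOrder(same, L = 20, s = 10, subjectId = "same")
  for (m in fcMatrices(fc)) expect_equal(m, matrix(1, 4, 4))
  set.seed(6)
  noise <- matrix(rnorm(8 * 4000), 8)
  fcN <- buildLowOrder(noise, L = 400, s = 400, subjectId = "noise")
  off <- unlist(lapply(fcMatrices(fcN), function(m) m[upper.tri(m)]))
  expect_lt(abs(mean(off)), 3 / sqrt(400))
})

test_that("high-order networks match brute-force column cosines", {
  set.seed(7)
  low <- randomDynamicFC(R = 6, K = 3)
  hi <- buildHighOrder(low)
  expect_equal(fcOrder(hi), "high")
  for (k in 1:3) {
    C <- fcMatrices(low)[[k]]
    H <- fcMatrices(hi)[[k]]
    for (i in 1:6) for (j in 1:6) {
      if (i == j) { expect_equal(H[i, j], 1); next }
      hi_ <- C[, i]; hj <- C[, j]
      expect_equal(H[i, j],
                   sum(hi_ * hj) / sqrt(sum(hi_^2) * sum(hj^2)),
                   tolerance = 1e-12)
    }
  }
  expect_error(buildHighOrder(hi), "low-order")
})

test_that("high-order extremes: identical columns give 1, orthogonal give 0", {
  C <- diag(4)                      # columns orthogonal
  C[1, 2] <- C[2, 1] <- 0           # keep symmetric
  fc <- new("DynamicFC", subjectId = "o", order = "low", matrices = list(C))
  H <- fcMatrices(buildHighOrder(fc))[[1]]
  expect_equal(H[1, 2], 0)
  C2 <- matrix(1, 3, 3)             # identical columns
  fc2 <- new("DynamicFC", subjectId = "i", order = "low", matrices = list(C2))
  expect_equal(fcMatrices(buildHighOrder(fc2))[[1]], matrix(1, 3, 3))
})

test_that("FC construction is equivariant under region permutation", {
  set.seed(8)
  x <- matrix(rnorm(7 * 50), 7)
  perm <- sample(7)
  fcP <- buildLowOrder(x[perm, ], L = 20, s = 10, subjectId = "p")
  fc <- buildLowOrder(x, L = 20, s = 10, subjectId = "u")
  for (k in seq_along(fcMatrices(fc))) {
    expect_equal(fcMatrices(fcP)[[k]], fcMatrices(fc)[[k]][perm, perm],
                 tolerance = 1e-12)
    hiP <- fcMatrices(buildHighOrder(fcP))[[k]]
    hi <- fcMatrices(buildHighOrder(fc))[[k]]
    expect_equal(hiP, hi[perm, perm], tolerance = 1e-12)
  }
})

test_that("every FC matrix stays symmetric with unit diagonal in [-1, 1]", {
  sp <- fixtureSpec(seed = 9)
  co <- makeCohort(sp)
  fcs <- buildLowOrder(co, L = 20, s = 10)
  for (f in fcs@fc) for (m in fcMatrices(f)) {
    expect_true(isSymmetric(m))
    expect_equal(diag(m), rep(1, nrow(m)))
    expect_true(all(m >= -1 - 1e-9 & m <= 1 + 1e-9))
  }
})
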