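test_that("metrics reproduce direct arithmetic on the confusion counts", {
  perfect <- computeMetrics(c(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unname(metricValues(perfect)), rep(100, 6))

  r <- computeMetrics(c(TP = 3, TN = 2, FP = 1, FN = 0))
  v <- metricValues(r)
  expect_equal(unname(v["ACC"]), 100 * 5 / 6, tolerance = 1e-9)
  expect_equal(unname(v["TPR"]), 100)
  expect_equal(unname(v["TNR"]), 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(unname(v["PPV"]), 75)
  expect_equal(unname(v["NPV"]), 100)
  expect_equal(unname(v["F1"]), 100 * 6 / 7, tolerance = 1e-9)

  undef <- computeMetrics(c(TP = 0, TN = 4, FP = 1, FN = 0))
  expect_true(is.na(metricValues(undef)["TPR"]))   # zero denominator
  expect_error(computeMetrics(c(TP = -1, TN = 1, FP = 0, FN = 0)),
               "nonnegative")
  expect_error(computeMetrics(c(TP = 0, TN = 0, FP = 0, FN = 0)),
               "at least one")
})

test_that("algebraic identities hold for random confusion counts", {
  set.seed(51)
  for (r in 1:200) {
    counts <- c(TP = rpois(1, 5), TN = rpois(1, 5), FP = rpois(1, 3),
                FN = rpois(1, 3))
    if (sum(counts) == 0) next
    v <- metricValues(computeMetrics(counts))
    expect_equal(unname(v["ACC"]),
                 100 * (counts["TP"] + counts["TN"]) / sum(counts),
                 tolerance = 1e-12, ignore_attr = TRUE)
    if (!is.na(v["PPV"]) && !is.na(v["TPR"]) && v["PPV"] + v["TPR"] > 0)
      expect_equal(unname(v["F1"]),
                   2 * v["PPV"] * v["TPR"] / (v["PPV"] + v["TPR"]),
                   tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("confusion counts treat eMCI as the positive class", {
  truth <- factor(c("NC", "NC", "eMCI", "eMCI", "eMCI"),
                  levels = c("NC", "eMCI"))
  pred <- factor(c("NC", "eMCI", "eMCI", "NC", "eMCI"),
                 levels = c("NC", "eMCI"))
  cc <- confusionFromLabels(truth, pred)
  expect_equal(unname(cc), c(2L, 1L, 1L, 1L))  # TP TN FP FN
  expect_equal(sum(cc), length(truth))
})

test_that("partition tables validate coverage and uniqueness", {
  p <- makePartition(1:6, c("A", "A", "B", "B", "C", "C"))
  expect_equal(p[3], "B")
  expect_error(makePartition(c(1, 1, 2), c("A", "B", "C")), "exactly one")
  expect_error(makePartition(c(1, 3), c("A", "B")), "cover every region")
  tf <- file.path(tempdir(), "part.csv")
  write.csv(data.frame(region_index = 1:4,
                       network_label = c("DMN", "DMN", "VN", "VN")),
            tf, row.names = FALSE)
  expect_equal(readPartition(tf), c("DMN", "DMN", "VN", "VN"))
  expect_error(readPartition(tf, nRegionsExpected = 6), "expected 6")
})

test_that("network ablation degrades exactly the targeted regions", {
  set.seed(52)
  sp <- fixtureSpec(nRegions = 10, nPerGroup = 8, nTimepoints = 80,
                    effectNodes = 4, effectSize = 0.6, seed = 61)
  d <- tinyGraphData(sp, L = 30, s = 10)
  cfg <- trainConfig(epochs = 20, patience = 20, gcnHidden = 6,
                     lstmHidden = 12, lstmLayers = 2, batchSize = 16,
                     seed = 6)
  model <- trainModel(d$seqs, d$labels, cfg)
  partition <- c(rep("EFF", 4), rep("OTH", 4), rep("CER", 2))

  # a label assigned to no region is rejected; an empty ablation is identity
  expect_error(ablateNetwork(d$masked, d$labels, partition, "XXX", model),
               "unknown network")
  tab <- ablationTable(d$masked, d$labels, partition, model)
  expect_setequal(tab$network, c("EFF", "OTH", "CER"))
  expect_equal(attr(tab, "baselineACC") - tab$deltaACC, tab$ACC,
               tolerance = 1e-9)

  # ablating every network at once zeroes all features -> identical scores
  allGone <- d$masked
  allGone@fc <- lapply(allGone@fc, dwgnn:::ablateRegionsFC, regions = 1:10)
  seqsGone <- buildGraphSequence(allGone)
  pr <- predictModel(model, seqsGone)
  expect_equal(length(unique(pr$probEMCI)), 1)   # zero-input response
  feats <- nodeFeatures(seqsGone[[1]])
  expect_true(all(feats == 0))
})
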