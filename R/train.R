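#' Training configuration
#'
#' Assembles and validates the training hyperparameters. Defaults follow
#' the reference protocol where one is stated (Adam, learning rate 0.001,
#' batch size 64, up to 400 epochs, L2 regularization plus dropout, early
#' stopping on a dedicated validation set, two GCN hidden layers, three
#' LSTM hidden layers, ReLU); widths, regularization strengths, the
#' patience and the split are this package's own defaults and can be
#' overridden.
#'
#' @param epochs maximum training epochs (default 400).
#' @param learningRate Adam learning rate (default 0.001).
#' @param batchSize minibatch size (default 64).
#' @param l2 L2 penalty weight on all weight matrices (default 5e-4).
#' @param dropout dropout rate on LSTM layer outputs (default 0.5).
#' @param patience early-stopping patience in epochs without validation
#'   loss improvement (default 30).
#' @param split train/val/test fractions, must sum to 1 (default
#'   0.70/0.15/0.15, stratified by label).
#' @param gcnHidden width of the GCN hidden layer (default 16; the
#'   per-window GCN maps scalar node features 1 -> gcnHidden -> 1 so the
#'   window output is again one value per region).
#' @param lstmHidden LSTM hidden size per layer (default 64).
#' @param lstmLayers number of stacked LSTM layers (default 3).
#' @param seed integer seed controlling split, initialization, batch order
#'   and dropout.
#' @return a validated named list (class `dwgnnTrainConfig`).
#' @export
trainConfig <- function(epochs = 400L, learningRate = 0.001, batchSize = 64L,
                        l2 = 5e-4, dropout = 0.5, patience = 30L,
                        split = c(train = 0.70, val = 0.15, test = 0.15),
                        gcnHidden = 16L, lstmHidden = 64L, lstmLayers = 3L,
                        seed = 1L) {
  stopifnot(epochs >= 1, learningRate > 0, batchSize >= 1, l2 >= 0,
            dropout >= 0, dropout < 1, patience >= 1,
            length(split) == 3, all(split > 0),
            abs(sum(split) - 1) < 1e-8,
            gcnHidden >= 1, lstmHidden >= 1, lstmLayers >= 1)
  cfg <- list(epochs = as.integer(epochs), learningRate = learningRate,
              batchSize = as.integer(batchSize), l2 = l2, dropout = dropout,
              patience = as.integer(patience),
              split = stats::setNames(as.numeric(split),
                                      c("train", "val", "test")),
              gcnWidths = c(1L, as.integer(gcnHidden), 1L),
              lstmHidden = as.integer(lstmHidden),
              lstmLayers = as.integer(lstmLayers), seed = as.integer(seed))
  class(cfg) <- "dwgnnTrainConfig"
  cfg
}

#' Stratified train/validation/test split
#'
#' Splits subject indices by label so each split preserves the group
#' proportions; the assignment is a pure function of `(labels, fractions,
#' seed)`.
#'
#' @param labels factor of group labels.
#' @param fractions length-3 numeric summing to 1 (train, val, test).
#' @param seed integer seed.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
stratifiedSplit <- function(labels, fractions = c(0.70, 0.15, 0.15),
                            seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  withSeed(seed, {
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      n <- length(idx)
      nTest <- max(1L, round(fractions[3] * n))
      nVal <- max(1L, round(fractions[2] * n))
      if (nTest + nVal >= n)
        stop(sprintf("degenerate split: label %s has only %d subjects", lv, n))
      out$test <- c(out$test, idx[seq_len(nTest)])
      out$val <- c(out$val, idx[nTest + seq_len(nVal)])
      out$train <- c(out$train, idx[(nTest + nVal + 1):n])
    }
  })
  lapply(out, sort)
}

adamInit <- function(params) {
  v <- packParams(params)
  list(m = numeric(length(v)), v = numeric(length(v)), t = 0L)
}

adamStep <- function(paramVec, gradVec, state, lr, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * gradVec
  state$v <- beta2 * state$v + (1 - beta2) * gradVec^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(param = paramVec - lr * mhat / (sqrt(vhat) + eps), state = state)
}

evalSplit <- function(params, data, y, config) {
  n <- length(data)
  probs <- matrix(NA_real_, n, 2)
  bs <- config$batchSize
  for (start in seq(1, n, by = bs)) {
    idx <- start:min(start + bs - 1, n)
    fw <- engineForward(params, data[idx], config,
                        y = if (is.null(y)) NULL else y[idx], train = FALSE)
    probs[idx, ] <- fw$probs
  }
  loss <- if (is.null(y)) NA_real_ else
    -mean(log(pmax(probs[cbind(seq_len(n), y)], 1e-12)))
  pred <- max.col(probs, ties.method = "first")
  list(probs = probs, pred = pred, loss = loss,
       acc = if (is.null(y)) NA_real_ else mean(pred == y))
}

#' Train the dynamically weighted GCN-LSTM classifier
#'
#' Minimizes softmax cross-entropy with an L2 penalty and dropout by Adam,
#' monitoring a dedicated validation split for early stopping and
#' returning the best-validation checkpoint. The split, parameter
#' initialization, batch order and dropout masks are all derived from
#' `config$seed`, so the result is a pure function of (data, labels,
#' config).
#'
#' @param seqs list of [GraphSequence-class] objects (whole cohort).
#' @param labels factor with levels `NC`, `eMCI` aligned with `seqs`.
#' @param config a [trainConfig()] list.
#' @param split optional list of `train`/`val`/`test` index vectors; when
#'   omitted a stratified split is drawn from `config$seed`. Test indices
#'   are carried along untouched for later evaluation.
#' @return a [DwGnnModel-class]; the resolved split is stored in
#'   `model@config$splitIndices` and the per-epoch history in
#'   `model@history`.
#' @export
trainModel <- function(seqs, labels, config = trainConfig(), split = NULL) {
  stopifnot(length(seqs) == length(labels))
  labels <- factor(labels, levels = GROUP_LEVELS)
  if (is.null(split))
    split <- stratifiedSplit(labels, config$split, config$seed)
  if (length(split$train) == 0 || length(split$val) == 0)
    stop("degenerate split: empty train or validation set")
  if (nlevels(droplevels(labels[split$train])) < 2)
    stop("training split must contain both classes")

  data <- prepGraphData(seqs)
  y <- as.integer(labels)
  R <- data[[1]]$R

  withSeed(config$seed, {
    params <- initParams(config, R)
    opt <- adamInit(params)
    skeleton <- params
    best <- list(loss = Inf, vec = packParams(params), epoch = 0L)
    hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                       trainAcc = numeric(0), valLoss = numeric(0),
                       valAcc = numeric(0))
    sinceBest <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(split$train)
      epLoss <- 0; epN <- 0L; epCorrect <- 0L
      for (start in seq(1, length(ord), by = config$batchSize)) {
        idx <- ord[start:min(start + config$batchSize - 1, length(ord))]
        res <- modelLossGrad(params, data[idx], y[idx], config, train = TRUE)
        upd <- adamStep(packParams(params), packParams(res$grads), opt,
                        config$learningRate)
        opt <- upd$state
        params <- unpackParams(upd$param, skeleton)
        epLoss <- epLoss + res$loss * length(idx)
        epN <- epN + length(idx)
        epCorrect <- epCorrect +
          sum(max.col(res$probs, ties.method = "first") == y[idx])
      }
      val <- evalSplit(params, data[split$val], y[split$val], config)
      hist <- rbind(hist, data.frame(
        epoch = epoch, trainLoss = epLoss / epN, trainAcc = epCorrect / epN,
        valLoss = val$loss, valAcc = val$acc))
      if (val$loss < best$loss - 1e-6) {
        best <- list(loss = val$loss, vec = packParams(params),
                     epoch = epoch)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config$patience) break
      }
    }
    params <- unpackParams(best$vec, skeleton)
  })

  cfgOut <- unclass(config)
  cfgOut$splitIndices <- split
  cfgOut$bestEpoch <- best$epoch
  new("DwGnnModel", params = params, config = cfgOut, history = hist,
      classLevels = GROUP_LEVELS)
}

#' Predict class scores and labels for graph sequences
#'
#' Deterministic inference pass (dropout disabled).
#'
#' @param model a trained [DwGnnModel-class].
#' @param seqs a [GraphSequence-class] or list of them.
#' @return data.frame with subject id, the two class probabilities and the
#'   predicted label.
#' @export
predictModel <- function(model, seqs) {
  if (is(seqs, "GraphSequence")) seqs <- list(seqs)
  data <- prepGraphData(seqs)
  cfg <- model@config
  ev <- evalSplit(model@params, data, NULL, cfg)
  data.frame(
    subjectId = vapply(seqs, function(s) s@subjectId, character(1)),
    probNC = ev$probs[, 1], probEMCI = ev$probs[, 2],
    predicted = factor(model@classLevels[ev$pred], levels = model@classLevels),
    row.names = NULL)
}

#' Evaluate a trained model on labelled graph sequences
#'
#' @param model a trained [DwGnnModel-class].
#' @param seqs list of [GraphSequence-class] objects.
#' @param labels factor with levels `NC`, `eMCI`.
#' @return a [MetricReport-class] (positive class eMCI).
#' @export
evaluateModel <- function(model, seqs, labels) {
  pred <- predictModel(model, seqs)$predicted
  computeMetrics(confusionFromLabels(factor(labels, levels = GROUP_LEVELS),
                                     pred))
}

#' Finite-difference gradient check
#'
#' Compares the analytic gradient of the full training loss (cross-entropy
#' plus L2, dropout disabled) against central finite differences on a
#' random subset of parameters. Used to validate the hand-written
#' backpropagation; returns the worst relative disagreement.
#'
#' @param seqs list of [GraphSequence-class] (tiny problems recommended).
#' @param labels factor with levels `NC`, `eMCI`.
#' @param config a [trainConfig()] list.
#' @param nCheck number of randomly chosen coordinates to probe.
#' @param h finite-difference step.
#' @param seed RNG seed for initialization and coordinate choice.
#' @return maximum relative error over the probed coordinates.
#' @export
gradientCheck <- function(seqs, labels, config = trainConfig(), nCheck = 60L,
                          h = 1e-5, seed = 1L) {
  data <- prepGraphData(seqs)
  y <- as.integer(factor(labels, levels = GROUP_LEVELS))
  withSeed(seed, {
    params <- initParams(config, data[[1]]$R)
    res <- modelLossGrad(params, data, y, config, train = FALSE)
    gvec <- packParams(res$grads)
    pvec <- packParams(params)
    coords <- sample(length(pvec), min(nCheck, length(pvec)))
    worst <- 0
    for (j in coords) {
      pp <- pvec; pp[j] <- pp[j] + h
      lp <- modelLossGrad(unpackParams(pp, params), data, y, config,
                          train = FALSE, wantGrad = FALSE)$loss
      pm <- pvec; pm[j] <- pm[j] - h
      lm <- modelLossGrad(unpackParams(pm, params), data, y, config,
                          train = FALSE, wantGrad = FALSE)$loss
      num <- (lp - lm) / (2 * h)
      rel <- abs(num - gvec[j]) / max(abs(num), abs(gvec[j]), 1e-8)
      worst <- max(worst, rel)
    }
    worst
  })
}
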