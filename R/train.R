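## Training harness: Adam optimization of the AAM-softmax objective with
## plateau learning-rate reduction and early stopping, checkpoint selection
## by validation Macro-F1, plus the grouped-CV / LOSO / ablation drivers.

#' Training configuration
#'
#' @param learningRate initial Adam step size (default 0.001).
#' @param batchSize samples per gradient step (default 16).
#' @param maxEpochs maximum epochs (default 100).
#' @param seed seed for initialization, data order and dropout (default 42).
#' @param earlyStopPatience epochs without validation improvement before
#'   stopping (default 15).
#' @param schedulerPatience epochs without improvement before the learning
#'   rate is reduced (default 5).
#' @param schedulerFactor multiplicative learning-rate reduction (default 0.5).
#' @return a `TrainConfig` list.
#' @export
trainConfig <- function(learningRate = 0.001, batchSize = 16, maxEpochs = 100,
                        seed = 42, earlyStopPatience = 15,
                        schedulerPatience = 5, schedulerFactor = 0.5) {
  stopifnot(learningRate > 0, batchSize >= 1, maxEpochs >= 1)
  structure(list(learningRate = learningRate, batchSize = batchSize,
                 maxEpochs = maxEpochs, seed = as.integer(seed),
                 earlyStopPatience = earlyStopPatience,
                 schedulerPatience = schedulerPatience,
                 schedulerFactor = schedulerFactor),
            class = "TrainConfig")
}

#' Precompute features for every manifest record
#'
#' Regenerates each clip, extracts the log-mel spectrogram, trims silence and
#' caches both the raw and the spectrally gated views plus the frame mask, so
#' epochs never recompute the front-end signal processing.
#'
#' @param manifest a [BarnManifest-class].
#' @param profiles class profiles used at generation time.
#' @param gating a [gatingConfig()] (must match the model's).
#' @param trimDb silence-trim threshold in dB (default 40).
#' @param nMels mel bins (default 80).
#' @return list (one element per record) of
#'   `list(raw, gated, mask, label, id)`.
#' @export
featureCache <- function(manifest, profiles = defaultProfiles(),
                         gating = gatingConfig(), trimDb = 40, nMels = 80) {
  r <- manifestRecords(manifest)
  lapply(seq_len(nrow(r)), function(i) {
    w <- synthRecordWave(manifest, i, profiles)
    sp <- computeLogMel(w, nMels = nMels)
    tr <- trimSilence(sp, trimDb)
    raw <- melValues(tr$spec)
    list(raw = raw, gated = gateValues(raw, gating),
         mask = maskBits(tr$mask), label = r$label[i], id = r$id[i])
  })
}

#' @keywords internal
adamInit <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0)
}

#' @keywords internal
adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' @keywords internal
accumGrads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

#' Train an ATF-Conformer on cached features
#'
#' Adam on the AAM-softmax loss with seeded determinism of initialization,
#' data order and dropout; plateau learning-rate reduction and early stopping
#' on validation Macro-F1; the checkpoint with the best validation Macro-F1
#' (earliest epoch on ties) is retained.
#'
#' @param modelCfg an [atfConfig()].
#' @param trainCfg a [trainConfig()].
#' @param features a [featureCache()] list.
#' @param trainIdx,valIdx integer indices into `features`.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best checkpoint), `record` (per-epoch history
#'   data.frame), `bestEpoch`, `bestValMacroF1`.
#' @export
trainModel <- function(modelCfg, trainCfg, features, trainIdx, valIdx,
                       verbose = FALSE) {
  labels <- vapply(features, function(f) f$label, character(1))
  labIdx <- match(labels, pigClasses())
  model <- atfInit(modelCfg, seed = trainCfg$seed)
  opt <- adamInit(model$params)
  lr <- trainCfg$learningRate
  best <- list(f1 = -Inf, epoch = 0L, params = model$params,
               bn = model$bnState)
  schedWait <- 0L
  stopWait <- 0L
  hist <- list()

  set.seed(deriveSeed(trainCfg$seed, 777))
  for (epoch in seq_len(trainCfg$maxEpochs)) {
    ord <- sample(trainIdx)
    nb <- ceiling(length(ord) / trainCfg$batchSize)
    epochLoss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * trainCfg$batchSize + 1):min(b * trainCfg$batchSize,
                                                        length(ord))]
      acc <- NULL
      for (i in idx) {
        f <- features[[i]]
        V <- if (modelCfg$useGating) f$gated else f$raw
        lg <- atfLossGrad(model, V, f$mask, labIdx[i], training = TRUE,
                          applyGating = FALSE)
        if (!is.finite(lg$loss)) stopInvalid("divergence: non-finite loss")
        model$bnState <- lg$bnNew
        acc <- accumGrads(acc, lg$grads)
        epochLoss <- epochLoss + lg$loss
      }
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(idx)
      upd <- adamStep(model$params, acc, opt, lr)
      model$params <- upd$params
      opt <- upd$state
    }
    epochLoss <- epochLoss / length(ord)

    pv <- atfPredict(model, features, valIdx)
    f1 <- macroF1Quick(labels[valIdx], pv$labels)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = epochLoss,
                                val_macro_f1 = f1, lr = lr)
    if (verbose)
      message(sprintf("epoch %d loss %.4f val macro-F1 %.2f lr %.2g",
                      epoch, epochLoss, f1, lr))

    if (f1 > best$f1 + 1e-9) {
      best <- list(f1 = f1, epoch = epoch, params = model$params,
                   bn = model$bnState)
      schedWait <- 0L
      stopWait <- 0L
    } else {
      schedWait <- schedWait + 1L
      stopWait <- stopWait + 1L
      if (schedWait >= trainCfg$schedulerPatience) {
        lr <- lr * trainCfg$schedulerFactor
        schedWait <- 0L
      }
      if (stopWait >= trainCfg$earlyStopPatience) break
    }
  }
  model$params <- best$params
  model$bnState <- best$bn
  list(model = model, record = do.call(rbind, hist),
       bestEpoch = best$epoch, bestValMacroF1 = best$f1)
}

#' Train on a grouped holdout split, with leakage check
#'
#' Refuses to train if any group token or pig identity spans partitions.
#'
#' @inheritParams trainModel
#' @param manifest a [BarnManifest-class].
#' @param split assignment from [groupedHoldoutSplit()].
#' @param features optional precomputed [featureCache()].
#' @param profiles class profiles for feature computation.
#' @return list with the training `run`, `testMetrics` (a `MetricsReport`
#'   or NULL if the split has no test partition) and `features`.
#' @export
trainOnSplit <- function(modelCfg, trainCfg, manifest, split, features = NULL,
                         profiles = defaultProfiles()) {
  assertNoLeakage(manifest, split)
  if (is.null(features))
    features <- featureCache(manifest, profiles, modelCfg$gating)
  r <- manifestRecords(manifest)
  part <- split[r$id]
  run <- trainModel(modelCfg, trainCfg, features,
                    which(part == "train"), which(part == "val"))
  testMetrics <- NULL
  testIdx <- which(part == "test")
  if (length(testIdx)) {
    pv <- atfPredict(run$model, features, testIdx)
    testMetrics <- computeMetrics(r$label[testIdx], pv$labels, pv$probs)
  }
  list(run = run, testMetrics = testMetrics, features = features)
}

#' Grouped k-fold cross-validation with out-of-fold predictions
#'
#' Trains one model per fold (remaining folds = train, held fold =
#' validation and evaluation, with within-fold checkpoint selection),
#' reports per-fold metrics, their mean and SD, and the out-of-fold
#' confusion matrix in which each sample is predicted exactly once by a
#' model not trained on its group.
#'
#' @inheritParams trainOnSplit
#' @param k number of folds (default 5).
#' @return list with `folds` (per-fold `MetricsReport`s), `summary`
#'   (data.frame of mean/sd), `oof` (data.frame id/y_true/y_pred),
#'   `oofProbs`, `confusion` and `oofMetrics`.
#' @export
runGroupedCv <- function(modelCfg, trainCfg, manifest, k = 5, features = NULL,
                         profiles = defaultProfiles()) {
  folds <- groupedKfold(manifest, k, seed = trainCfg$seed)
  assertNoLeakage(manifest, folds)
  if (is.null(features))
    features <- featureCache(manifest, profiles, modelCfg$gating)
  r <- manifestRecords(manifest)
  fold <- folds[r$id]
  foldMetrics <- vector("list", k)
  oof <- list()
  oofProbs <- list()
  for (f in seq_len(k)) {
    trainIdx <- which(fold != f)
    valIdx <- which(fold == f)
    tc <- trainCfg
    tc$seed <- deriveSeed(trainCfg$seed, f)
    run <- trainModel(modelCfg, tc, features, trainIdx, valIdx)
    pv <- atfPredict(run$model, features, valIdx)
    foldMetrics[[f]] <- computeMetrics(r$label[valIdx], pv$labels, pv$probs)
    oof[[f]] <- data.frame(id = r$id[valIdx], y_true = r$label[valIdx],
                           y_pred = pv$labels, fold = f,
                           stringsAsFactors = FALSE)
    oofProbs[[f]] <- pv$probs
  }
  pick <- function(m, what) vapply(m, function(x) x[[what]], numeric(1))
  summ <- do.call(rbind, lapply(
    c("accuracy", "macro_precision", "macro_recall", "macro_f1", "macro_auroc"),
    function(w) data.frame(metric = w, mean = mean(pick(foldMetrics, w)),
                           sd = stats::sd(pick(foldMetrics, w)))))
  oofDf <- do.call(rbind, oof)
  probs <- do.call(rbind, oofProbs)
  list(folds = foldMetrics, summary = summ, oof = oofDf, oofProbs = probs,
       confusion = oofConfusion(oof),
       oofMetrics = computeMetrics(oofDf$y_true, oofDf$y_pred, probs))
}

#' Leave-one-session-out evaluation
#'
#' Three trainings, each holding out one recording session as the test
#' domain; train/validation subdivision happens only inside the non-test
#' sessions. Returns the session summary with the noon-degradation
#' statistic.
#'
#' @inheritParams trainOnSplit
#' @param valRatio validation fraction within non-test sessions.
#' @return list with `report` (a [sessionSummary()]) and `perSession`
#'   (`MetricsReport` per session).
#' @export
runLoso <- function(modelCfg, trainCfg, manifest, features = NULL,
                    valRatio = 1 / 9, profiles = defaultProfiles()) {
  splits <- losoBySession(manifest, valRatio, seed = trainCfg$seed)
  if (is.null(features))
    features <- featureCache(manifest, profiles, modelCfg$gating)
  r <- manifestRecords(manifest)
  perSession <- list()
  f1s <- c(morning = NA_real_, noon = NA_real_, evening = NA_real_)
  for (s in names(splits)) {
    assertNoLeakage(manifest, splits[[s]])
    part <- splits[[s]][r$id]
    tc <- trainCfg
    tc$seed <- deriveSeed(trainCfg$seed, match(s, names(splits)))
    run <- trainModel(modelCfg, tc, features,
                      which(part == "train"), which(part == "val"))
    testIdx <- which(part == "test")
    pv <- atfPredict(run$model, features, testIdx)
    perSession[[s]] <- computeMetrics(r$label[testIdx], pv$labels, pv$probs)
    f1s[[s]] <- perSession[[s]]$macro_f1
  }
  list(report = sessionSummary(f1s), perSession = perSession)
}

#' @keywords internal
ablationVariants <- function(baseCfg) {
  v <- list()
  v[["full"]] <- baseCfg
  cfg <- baseCfg; cfg$useGating <- FALSE; v[["no_gating"]] <- cfg
  cfg <- baseCfg; cfg$useTa <- FALSE; v[["no_ta"]] <- cfg
  cfg <- baseCfg; cfg$useTfd <- FALSE; v[["no_tfd"]] <- cfg
  cfg <- baseCfg; cfg$convFrontOnly <- FALSE
  cfg$convFrontOnly <- TRUE; cfg$useTa <- FALSE; v[["conv_front_only"]] <- cfg
  v
}

#' Single-removal ablation suite
#'
#' Trains and evaluates the full model and the four single-removal variants
#' (no spectral gating, no triplet attention, standard symmetric Conformer
#' block instead of the decoupled one, conv front end only) on identical
#' splits, features and seeds.
#'
#' @inheritParams trainOnSplit
#' @param seeds integer vector of training seeds (default the train config
#'   seed).
#' @return data.frame with one row per variant x seed (accuracy, macro
#'   precision/recall/F1 on the held-out test partition, parameter count).
#' @export
runAblationSuite <- function(baseCfg, trainCfg, manifest, features = NULL,
                             seeds = trainCfg$seed,
                             profiles = defaultProfiles()) {
  split <- groupedHoldoutSplit(manifest, seed = trainCfg$seed)
  assertNoLeakage(manifest, split)
  if (is.null(features))
    features <- featureCache(manifest, profiles, baseCfg$gating)
  variants <- ablationVariants(baseCfg)
  rows <- list()
  for (vn in names(variants)) {
    for (sd in seeds) {
      tc <- trainCfg
      tc$seed <- as.integer(sd)
      res <- trainOnSplit(variants[[vn]], tc, manifest, split, features)
      m <- res$testMetrics
      rows[[length(rows) + 1]] <- data.frame(
        variant = vn, seed = sd, accuracy = m$accuracy,
        macro_precision = m$macro_precision, macro_recall = m$macro_recall,
        macro_f1 = m$macro_f1, n_params = atfParamCount(variants[[vn]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
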