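## Inference-time robustness and probe protocols: additive-noise sweeps with
## group-exclusive noise selection, and the linear background-separability
## probe under grouped cross-validation.

#' Additive-noise robustness sweep
#'
#' For each SNR level every test clip is mixed with a noise-pool segment
#' whose group token differs from the clip's (session-level exclusivity),
#' features are recomputed with the shared pipeline, and Macro-F1 is
#' measured without retraining or threshold recalibration.
#'
#' @param model a trained `AtfModel`.
#' @param manifest the [BarnManifest-class] the clips come from.
#' @param testIdx record indices to evaluate.
#' @param noisePool list from [synthesizeNoisePool()].
#' @param snrBins numeric SNR levels in dB (default `c(10, 5, 0, -5)`).
#' @param profiles class profiles.
#' @param seed seed for the noise-segment draw.
#' @param trimDb silence-trim threshold.
#' @return list with `curve` (data.frame `snr_db`, `macro_f1`) and `clean`
#'   (Macro-F1 without added noise).
#' @export
noiseRobustnessSweep <- function(model, manifest, testIdx, noisePool,
                                 snrBins = c(10, 5, 0, -5),
                                 profiles = defaultProfiles(), seed = 1,
                                 trimDb = 40) {
  r <- manifestRecords(manifest)
  tok <- assignGroups(manifest)
  noiseTok <- vapply(noisePool, function(n)
    paste("grp", n$key$pen_id, n$key$date, n$key$session, sep = ":"),
    character(1))
  yTrue <- r$label[testIdx]

  predictWave <- function(w) {
    sp <- computeLogMel(w, nMels = model$cfg$nMels)
    tr <- trimSilence(sp, trimDb)
    fw <- atfForward(model, tr$spec, tr$mask, training = FALSE)
    fw$predLabel
  }

  waves <- lapply(testIdx, function(i) synthRecordWave(manifest, i, profiles))
  clean <- macroF1Quick(yTrue, vapply(waves, predictWave, character(1)))

  curve <- data.frame(snr_db = numeric(0), macro_f1 = numeric(0))
  for (b in seq_along(snrBins)) {
    snr <- snrBins[b]
    preds <- withLocalSeed(deriveSeed(seed, b), {
      vapply(seq_along(testIdx), function(j) {
        i <- testIdx[j]
        ok <- which(noiseTok != tok[[r$id[i]]])
        if (length(ok) == 0)
          stopInvalid("no group-exclusive noise segment for sample ", r$id[i])
        n <- noisePool[[ok[sample.int(length(ok), 1)]]]
        predictWave(mixAtSnr(waves[[j]], n$wave, snr))
      }, character(1))
    })
    curve <- rbind(curve,
                   data.frame(snr_db = snr, macro_f1 = macroF1Quick(yTrue, preds)))
  }
  list(curve = curve, clean = clean)
}

#' Background-separability probe
#'
#' Trains a ridge-regularized linear classifier on time-averaged log-mel
#' features under grouped cross-validation (no group spans folds) and
#' reports balanced accuracy and AUROC. Used to check whether two recording
#' environments are distinguishable from their non-event background alone.
#'
#' @param featMatrix numeric matrix, one row per background segment
#'   (e.g. time-averaged log-mel vectors).
#' @param regionLabels two-level label vector (recording region per segment).
#' @param groups group token per segment.
#' @param k folds (default 5).
#' @param seed fold shuffle seed.
#' @param lambda ridge penalty (default 0.05).
#' @return list with `balanced_accuracy` and `auroc`.
#' @export
backgroundProbe <- function(featMatrix, regionLabels, groups, k = 5,
                            seed = 1, lambda = 0.05) {
  regionLabels <- as.character(regionLabels)
  lev <- sort(unique(regionLabels))
  if (length(lev) != 2) stopInvalid("need exactly two region labels")
  y <- as.integer(regionLabels == lev[2])
  fold <- tokensToFolds(groups, k, seed)
  score <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    if (length(te) == 0) next
    if (length(unique(y[tr])) < 2) {
      score[te] <- 0.5
      next
    }
    # desk-scale probes run on few segments per fold; glmnet's small-n
    # advisory warning is expected there
    fit <- suppressWarnings(
      glmnet::glmnet(featMatrix[tr, , drop = FALSE], factor(y[tr]),
                     family = "binomial", alpha = 0, lambda = lambda,
                     standardize = TRUE))
    score[te] <- as.numeric(stats::predict(fit,
                                           featMatrix[te, , drop = FALSE],
                                           type = "response"))
  }
  pred <- as.integer(score >= 0.5)
  recall1 <- if (sum(y == 1) > 0) mean(pred[y == 1] == 1) else NA
  recall0 <- if (sum(y == 0) > 0) mean(pred[y == 0] == 0) else NA
  list(balanced_accuracy = mean(c(recall0, recall1), na.rm = TRUE),
       auroc = rankAuroc(score, y == 1))
}

#' Time-averaged log-mel feature vector of a waveform
#'
#' Convenience feature extractor for [backgroundProbe()].
#'
#' @param w a [Waveform-class].
#' @param nMels mel bins (default 80).
#' @return numeric vector of length `nMels`.
#' @export
meanMelFeature <- function(w, nMels = 80) {
  rowMeans(melValues(computeLogMel(w, nMels = nMels)))
}
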