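# Shared fixtures, memoized so expensive objects are built once per run.
.fx <- new.env(parent = emptyenv())

memoFixture <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# small barn dataset: 20 clips per class, the generator's default conditions
fixtureManifest <- function() {
  memoFixture("man100", function() generateDataset(nPerClass = 20, seed = 42))
}

fixtureFeatures <- function() {
  memoFixture("feats100", function() featureCache(fixtureManifest()))
}

# reduced-width architecture used for desk-scale training runs
tinyAtfConfig <- function(...) {
  atfConfig(frontChannels = 4, modelDim = 64, nHeads = 4, nBlocks = 2,
            dropout = 0, ...)
}

# micro architecture for gradient checks
microAtfConfig <- function(...) {
  atfConfig(nMels = 8, frontChannels = 2, modelDim = 8, nHeads = 2,
            nBlocks = 1, freqKernel = 3, ffnExpansion = 2, dropout = 0,
            useGating = FALSE, ...)
}

# one trained model on the small dataset's grouped holdout split
fixtureTrainedModel <- function() {
  memoFixture("trained", function() {
    man <- fixtureManifest()
    feats <- fixtureFeatures()
    split <- groupedHoldoutSplit(man, seed = 42)
    part <- split[manifestRecords(man)$id]
    tc <- trainConfig(maxEpochs = 10, seed = 42, earlyStopPatience = 4,
                      schedulerPatience = 3)
    run <- trainModel(tinyAtfConfig(), tc, feats,
                      which(part == "train"), which(part == "val"))
    list(run = run, split = split, part = part)
  })
}

# brute-force per-class tally oracle for classification metrics
bruteForceMetrics <- function(yTrue, yPred, classes = pigClasses()) {
  present <- classes[classes %in% yTrue]
  perClass <- t(vapply(classes, function(cl) {
    tp <- sum(yTrue == cl & yPred == cl)
    fp <- sum(yTrue != cl & yPred == cl)
    fn <- sum(yTrue == cl & yPred != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f <- if (is.na(r)) NA_real_ else if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p = p, r = r, f = f)
  }, numeric(3)))
  keep <- classes %in% present
  list(accuracy = 100 * mean(yTrue == yPred),
       macro_precision = 100 * mean(perClass[keep, "p"]),
       macro_recall = 100 * mean(perClass[keep, "r"]),
       macro_f1 = 100 * mean(perClass[keep, "f"]))
}

# spectral energy fraction of a waveform inside [lo, hi] Hz (periodogram)
bandEnergyFraction <- function(w, lo, hi) {
  x <- samples(w)
  sr <- sampleRate(w)
  sp <- Mod(stats::fft(x))^2
  n <- length(x)
  freqs <- (seq_len(n) - 1) * sr / n
  half <- freqs <= sr / 2
  sum(sp[half & freqs >= lo & freqs <= hi]) / sum(sp[half])
}
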