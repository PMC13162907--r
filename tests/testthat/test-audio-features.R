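test_that("resampling doubles an 8 kHz second to 16000 samples with peak 1", {
  t <- seq(0, 1 - 1 / 8000, by = 1 / 8000)
  w <- Waveform(0.3 * sin(2 * pi * 440 * t), 8000)
  out <- resampleNormalize(w, 16000)
  expect_equal(sampleRate(out), 16000)
  expect_equal(length(samples(out)), 16000)
  expect_equal(max(abs(samples(out))), 1)
})

test_that("all-zero input normalizes to itself without blowing up", {
  out <- resampleNormalize(Waveform(numeric(100), 16000))
  expect_equal(samples(out), numeric(100))
})

test_that("peak normalization at the target rate is exact scalar multiplication", {
  set.seed(1)
  x <- 0.25 * stats::runif(500, -1, 1)
  x[137] <- 0.25
  out <- resampleNormalize(Waveform(x, 16000))
  expect_equal(samples(out), x / 0.25, tolerance = 1e-12)
})

test_that("frame count follows T = 1 + floor((N - win)/hop) with no centering", {
  w <- Waveform(stats::rnorm(16000), 16000)
  sp <- computeLogMel(w)
  expect_equal(nMels(sp), 80)
  expect_equal(nFrames(sp), 98)
  # a second of audio plus one extra hop adds exactly one frame
  w2 <- Waveform(stats::rnorm(16160), 16000)
  expect_equal(nFrames(computeLogMel(w2)), 99)
  expect_error(computeLogMel(Waveform(stats::rnorm(300), 16000)), "window")
})

test_that("all-zero waveform gives the constant log floor", {
  sp <- computeLogMel(Waveform(numeric(8000), 16000))
  expect_true(all(melValues(sp) == log(1e-10)))
})

test_that("a pure tone peaks in the mel bin whose center is nearest the tone", {
  f0 <- 1000
  t <- seq(0, 1 - 1 / 16000, by = 1 / 16000)
  sp <- computeLogMel(Waveform(sin(2 * pi * f0 * t), 16000))
  hot <- which.max(rowMeans(melValues(sp)))
  # independent mel-scale oracle for filter centers
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  centers <- imel(seq(mel(0), mel(8000), length.out = 82))[2:81]
  expect_equal(hot, which.min(abs(centers - f0)))
})

test_that("log-mel extraction is bit-identical across calls", {
  w <- Waveform(stats::rnorm(12000), 16000)
  expect_identical(melValues(computeLogMel(w)), melValues(computeLogMel(w)))
})

test_that("silence trimming removes exactly the frames a threshold scan flags", {
  loud <- matrix(stats::rnorm(80 * 50, mean = 2), 80, 50)
  quiet <- matrix(log(1e-10), 80, 10)
  V <- cbind(quiet, loud, quiet)
  sp <- new("MelSpectrogram", values = V, sampleRate = 16000, frameLenMs = 25,
            hopMs = 10, fminHz = 0, fmaxHz = 8000)
  tr <- trimSilence(sp, 40)
  # brute-force scan oracle
  e <- 10 * log10(colSums(exp(V)))
  keep <- which(e >= max(e) - 40)
  expect_equal(nFrames(tr$spec), max(keep) - min(keep) + 1)
  expect_equal(nFrames(tr$spec), 50)
  # slice-only contract: retained values are untouched
  expect_identical(melValues(tr$spec), V[, min(keep):max(keep)])
})

test_that("trimming keeps loud inputs intact and errors on silence", {
  V <- matrix(stats::rnorm(80 * 20, mean = 2), 80, 20)
  sp <- new("MelSpectrogram", values = V, sampleRate = 16000, frameLenMs = 25,
            hopMs = 10, fminHz = 0, fmaxHz = 8000)
  tr <- trimSilence(sp, 40)
  expect_identical(melValues(tr$spec), V)
  expect_true(all(maskBits(tr$mask) == 1))
  # idempotence: trimming a trimmed spectrogram changes nothing
  tr2 <- trimSilence(tr$spec, 40)
  expect_identical(melValues(tr2$spec), melValues(tr$spec))
  flat <- new("MelSpectrogram", values = matrix(0, 80, 10), sampleRate = 16000,
              frameLenMs = 25, hopMs = 10, fminHz = 0, fmaxHz = 8000)
  # a constant spectrogram has no frame 40 dB below the max
  expect_identical(nFrames(trimSilence(flat, 40)$spec), 10L)
})

test_that("gate gains stay in [minGain, 1] and spare high-energy cells", {
  set.seed(2)
  V <- matrix(stats::rnorm(80 * 40, 0, 0.3), 80, 40)
  V[30, 17] <- 8
  sp <- new("MelSpectrogram", values = V, sampleRate = 16000, frameLenMs = 25,
            hopMs = 10, fminHz = 0, fmaxHz = 8000)
  cfg <- gatingConfig()
  g <- spectralGateGain(sp, cfg)
  expect_true(all(g >= cfg$minGain & g <= 1))
  # direct mask-formula oracle for one cell: sigmoid gain on the
  # floor-referenced excess, applied multiplicatively to mel power
  dbn <- 10 / log(10)
  fl <- stats::quantile(V[30, ] * dbn, 0.2, names = FALSE)
  expected <- cfg$minGain + (1 - cfg$minGain) /
    (1 + exp(-((V[30, 17] * dbn - fl - 3) * 1)))
  expect_equal(g[30, 17], expected, tolerance = 1e-12)
  gated <- melValues(spectralGate(sp, cfg))
  expect_equal(gated[30, 17], V[30, 17] + log(expected), tolerance = 1e-12)
  # the loud cell is attenuated less than its row's noise cells
  att <- melValues(sp) - gated
  expect_true(all(att >= 0))
  expect_lt(att[30, 17], min(att[30, -17]))
})

test_that("minGain = 1 disables gating exactly", {
  V <- matrix(stats::rnorm(80 * 30), 80, 30)
  sp <- new("MelSpectrogram", values = V, sampleRate = 16000, frameLenMs = 25,
            hopMs = 10, fminHz = 0, fmaxHz = 8000)
  out <- spectralGate(sp, gatingConfig(minGain = 1))
  expect_equal(melValues(out), V, tolerance = 1e-12)
})

test_that("gate gain is monotone in the cell value for a fixed floor", {
  cfg <- gatingConfig()
  base <- matrix(stats::rnorm(80 * 30), 80, 30)
  sp1 <- new("MelSpectrogram", values = base, sampleRate = 16000,
             frameLenMs = 25, hopMs = 10, fminHz = 0, fmaxHz = 8000)
  g1 <- spectralGateGain(sp1, cfg)
  for (v in c(0.5, 1, 2)) {
    b2 <- base
    b2[10, 5] <- base[10, 5] + v
    # keep the row's floor fixed by raising a high-quantile cell only
    sp2 <- new("MelSpectrogram", values = b2, sampleRate = 16000,
               frameLenMs = 25, hopMs = 10, fminHz = 0, fmaxHz = 8000)
    g2 <- spectralGateGain(sp2, cfg)
    expect_gte(g2[10, 5], g1[10, 5])
  }
})

test_that("dominant band covers band-limited noise and spans white noise", {
  set.seed(3)
  specs <- lapply(1:4, function(i) {
    w <- synthesizeEvent(classProfile("x", c(1000, 3000), c(1.5, 0.05),
                                      "continuous", eventSnrDb = 40), i)
    computeLogMel(w)
  })
  band <- estimateDominantBand(specs)
  expect_lte(band[["lo_hz"]], 1000)
  expect_gte(band[["lo_hz"]], 400)
  expect_gte(band[["hi_hz"]], 3000)
  expect_lte(band[["hi_hz"]], 3600)

  white <- lapply(1:3, function(i)
    computeLogMel(Waveform(stats::rnorm(16000), 16000)))
  wband <- estimateDominantBand(white)
  expect_lt(wband[["lo_hz"]], 300)
  expect_gt(wband[["hi_hz"]], 7000)
  expect_error(estimateDominantBand(list()), "at least one")
})

test_that("synthetic cough clips concentrate energy near the cough band", {
  p <- defaultProfiles()$cough
  specs <- lapply(1:5, function(i) computeLogMel(synthesizeEvent(p, 100 + i)))
  band <- estimateDominantBand(specs)
  # overlap with the nominal 0.8-3.0 kHz band
  expect_lt(band[["lo_hz"]], 3000)
  expect_gt(band[["hi_hz"]], 800)
})
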