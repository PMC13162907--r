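## Shared input pipeline: resampling, log-mel extraction, silence trimming and
## adaptive spectral gating. Framing uses no center padding, so frame counts
## obey T = 1 + floor((N - win) / hop) exactly.

LOG_MEL_FLOOR <- 1e-10      # additive floor on mel power before log
DB_PER_NAT <- 10 / log(10)  # natural-log power -> dB

#' Resample to a target rate and peak-normalize
#'
#' Brings a clip to the canonical 16 kHz mono representation and scales it so
#' the peak amplitude is 1. An all-zero waveform passes through unchanged
#' (there is nothing to normalize against).
#'
#' @param w a [Waveform-class].
#' @param targetRate target sampling rate in Hz (default 16000).
#' @return a [Waveform-class] at `targetRate` with peak |amplitude| = 1.
#' @export
resampleNormalize <- function(w, targetRate = 16000) {
  stopifnot(is(w, "Waveform"))
  x <- samples(w)
  if (sampleRate(w) != targetRate) {
    g <- gcd2(targetRate, sampleRate(w))
    x <- as.numeric(signal::resample(x, targetRate / g, sampleRate(w) / g))
  }
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  Waveform(x, targetRate)
}

#' @keywords internal
gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' @keywords internal
hz2mel <- function(f) 2595 * log10(1 + f / 700)

#' @keywords internal
mel2hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filterbank matrix and band edges
#'
#' Triangular mel filters over an FFT power spectrum, HTK-style mel scale.
#'
#' @param nMels number of mel bands.
#' @param nFft FFT length.
#' @param sr sampling rate in Hz.
#' @param fmin,fmax filterbank frequency range in Hz.
#' @return list with `weights` (nMels x (nFft/2 + 1)) and `edgesHz`
#'   (nMels + 2 band edge frequencies).
#' @export
melFilterbank <- function(nMels = 80, nFft = 512, sr = 16000,
                          fmin = 0, fmax = 8000) {
  freqs <- (0:(nFft / 2)) * sr / nFft
  edges <- mel2hz(seq(hz2mel(fmin), hz2mel(fmax), length.out = nMels + 2))
  W <- matrix(0, nMels, length(freqs))
  for (i in seq_len(nMels)) {
    lo <- edges[i]; mid <- edges[i + 1]; hi <- edges[i + 2]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    W[i, ] <- pmax(0, pmin(up, down))
  }
  list(weights = W, edgesHz = edges)
}

#' Compute an 80-band log-mel spectrogram
#'
#' STFT with a periodic Hann window, 25 ms frames, 10 ms hop and no center
#' padding, followed by a mel filterbank over 0-8 kHz and a natural log with
#' additive floor `1e-10` on power. The frame count is
#' `T = 1 + floor((N - win) / hop)`.
#'
#' @param w a [Waveform-class] at 16 kHz.
#' @param nMels number of mel bands (default 80).
#' @param frameLenMs window length in ms (default 25).
#' @param hopMs hop in ms (default 10).
#' @param fminHz,fmaxHz filterbank range in Hz (defaults 0 and 8000).
#' @return a [MelSpectrogram-class].
#' @export
computeLogMel <- function(w, nMels = 80, frameLenMs = 25, hopMs = 10,
                          fminHz = 0, fmaxHz = 8000) {
  stopifnot(is(w, "Waveform"))
  sr <- sampleRate(w)
  x <- samples(w)
  win <- round(sr * frameLenMs / 1000)
  hop <- round(sr * hopMs / 1000)
  n <- length(x)
  if (n < win)
    stopInvalid("waveform shorter than one analysis window (", win, " samples)")
  nT <- 1 + floor((n - win) / hop)
  nFft <- 2^ceiling(log2(win))

  idx <- outer(seq_len(win), (seq_len(nT) - 1) * hop, "+")
  frames <- matrix(x[idx], win, nT)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / win)
  frames <- frames * hann

  padded <- matrix(0, nFft, nT)
  padded[seq_len(win), ] <- frames
  spec <- stats::mvfft(padded)[seq_len(nFft / 2 + 1), , drop = FALSE]
  power <- Mod(spec)^2

  fb <- melFilterbank(nMels, nFft, sr, fminHz, fmaxHz)
  mel <- fb$weights %*% power
  newMelSpectrogram(log(mel + LOG_MEL_FLOOR), sr, frameLenMs, hopMs, fminHz, fmaxHz)
}

#' @keywords internal
frameEnergyDb <- function(values) 10 * log10(colSums(exp(values)))

#' Trim leading/trailing silent frames and build the frame mask
#'
#' A frame is silent when its total mel energy falls more than
#' `thresholdDb` below the loudest frame. Leading and trailing silent frames
#' are removed (slice only; retained values are untouched); residual silent
#' interior frames are flagged as 0 in the returned mask so masked pooling can
#' ignore them.
#'
#' @param spec a [MelSpectrogram-class].
#' @param thresholdDb energy threshold below the maximum frame energy, in dB
#'   (default 40).
#' @return list with `spec` (trimmed [MelSpectrogram-class]) and `mask`
#'   ([FrameMask-class] over the retained frames).
#' @export
trimSilence <- function(spec, thresholdDb = 40) {
  stopifnot(is(spec, "MelSpectrogram"))
  V <- melValues(spec)
  e <- frameEnergyDb(V)
  keep <- e >= max(e) - thresholdDb
  if (!any(keep)) stopInvalid("empty segment: all frames below the energy threshold")
  a <- which(keep)[1]
  b <- which(keep)[sum(keep)]
  sub <- V[, a:b, drop = FALSE]
  list(
    spec = newMelSpectrogram(sub, sampleRate(spec), spec@frameLenMs,
                             spec@hopMs, spec@fminHz, spec@fmaxHz),
    mask = FrameMask(as.integer(keep[a:b]))
  )
}

#' Spectral gating configuration
#'
#' @param noiseFloorPercentile per-mel-bin percentile used as the noise floor
#'   estimate (default 20).
#' @param thresholdOffsetDb dB above the floor where the gate is half open
#'   (default 3).
#' @param maskSlope sigmoid steepness in 1/dB (default 1).
#' @param minGain lower bound of the soft gate (default 0.1); `minGain = 1`
#'   disables gating.
#' @return list of gating parameters.
#' @export
gatingConfig <- function(noiseFloorPercentile = 20, thresholdOffsetDb = 3,
                         maskSlope = 1, minGain = 0.1) {
  stopifnot(noiseFloorPercentile > 0, noiseFloorPercentile < 100,
            minGain >= 0, minGain <= 1)
  list(noiseFloorPercentile = noiseFloorPercentile,
       thresholdOffsetDb = thresholdOffsetDb,
       maskSlope = maskSlope, minGain = minGain)
}

#' Adaptive spectral gating in the log-mel domain
#'
#' Estimates a per-mel-bin noise floor as a percentile of that bin's frame
#' values and multiplies each cell's mel power by a soft sigmoid gain in
#' `[minGain, 1]` of the cell's floor-referenced excess. Cells well above
#' the floor pass through nearly unchanged; noise-dominated cells are
#' attenuated by up to `10 log10(minGain)` dB. The same deterministic
#' transform is applied at train and inference time; `minGain = 1` is the
#' exact identity.
#'
#' @param spec a [MelSpectrogram-class] with at least 2 frames.
#' @param cfg a [gatingConfig()] list.
#' @return gated [MelSpectrogram-class].
#' @export
spectralGate <- function(spec, cfg = gatingConfig()) {
  stopifnot(is(spec, "MelSpectrogram"))
  V <- melValues(spec)
  newMelSpectrogram(gateValues(V, cfg), sampleRate(spec), spec@frameLenMs,
                    spec@hopMs, spec@fminHz, spec@fmaxHz)
}

# matrix-level gating core shared with the model's input stage: the soft
# gain multiplies mel power, i.e. adds log(gain) in the log-mel domain
#' @keywords internal
gateValues <- function(V, cfg) {
  log(gainValues(V, cfg)) + V
}

#' @keywords internal
gainValues <- function(V, cfg) {
  if (ncol(V) < 2) stopInvalid("spectral gating needs at least 2 frames")
  Vdb <- V * DB_PER_NAT
  floor_db <- apply(Vdb, 1, stats::quantile, probs = cfg$noiseFloorPercentile / 100,
                    names = FALSE)
  excess <- Vdb - floor_db
  cfg$minGain + (1 - cfg$minGain) *
    sigmoid((excess - cfg$thresholdOffsetDb) * cfg$maskSlope)
}

#' Gate gain matrix (diagnostic view of [spectralGate()])
#' @inheritParams spectralGate
#' @return matrix of per-cell multiplicative power gains in `[minGain, 1]`.
#' @export
spectralGateGain <- function(spec, cfg = gatingConfig()) {
  gainValues(melValues(spec), cfg)
}

#' Estimate the dominant energy band of a set of spectrograms
#'
#' Averages each spectrogram over time, averages the resulting profiles over
#' samples, normalizes each mel bin by its filter bandwidth (so wide
#' high-frequency filters do not dominate), and returns the contiguous mel
#' interval covering every bin whose mean power density exceeds `fraction`
#' of the peak bin, mapped back to Hz via the filterbank band edges.
#'
#' @param specs list of [MelSpectrogram-class] objects sharing `nMels`.
#' @param fraction of the peak mean power a bin must reach (default 0.25).
#' @return numeric `c(lo_hz, hi_hz)`.
#' @export
estimateDominantBand <- function(specs, fraction = 0.25) {
  if (length(specs) == 0) stopInvalid("need at least one spectrogram")
  nm <- nMels(specs[[1]])
  profs <- vapply(specs, function(s) {
    stopifnot(nMels(s) == nm)
    rowMeans(exp(melValues(s)))
  }, numeric(nm))
  s1 <- specs[[1]]
  fb <- melFilterbank(nm, sr = sampleRate(s1), fmin = s1@fminHz, fmax = s1@fmaxHz)
  prof <- rowMeans(profs) / rowSums(fb$weights)   # power density per bin
  hot <- which(prof >= fraction * max(prof))
  c(lo_hz = fb$edgesHz[min(hot)], hi_hz = fb$edgesHz[max(hot) + 2])
}
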