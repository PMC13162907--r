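## Seeded synthetic barn soundscapes: five class-specific event recipes
## (band-limited noise shaped by class-typical envelopes), a non-event noise
## pool, and manifest generation with pen x date x session group structure,
## pig-wise close-range cough groups and a session-dependent background shift.

#' Acoustic profile of one vocalization class
#'
#' @param name class name.
#' @param bandHz numeric `c(lo, hi)` dominant band in Hz.
#' @param durationS numeric `c(mean, spread)` clip duration in seconds.
#' @param envelope one of `"transient"`, `"sustained"`, `"rhythmic"`,
#'   `"continuous"`, `"ambient"`.
#' @param pulseRateHz pulse rate for rhythmic envelopes (Hz).
#' @param eventSnrDb event level over the barn background, in dB.
#' @return a `ClassProfile` list.
#' @export
classProfile <- function(name, bandHz, durationS, envelope,
                         pulseRateHz = NA_real_, eventSnrDb = 15) {
  stopifnot(bandHz[1] >= 0, bandHz[1] < bandHz[2], bandHz[2] <= 8000,
            durationS[1] >= 1, durationS[1] <= 2)
  structure(list(name = name, bandHz = bandHz, durationS = durationS,
                 envelope = envelope, pulseRateHz = pulseRateHz,
                 eventSnrDb = eventSnrDb),
            class = "ClassProfile")
}

#' Default acoustic profiles for the five classes
#'
#' Dominant bands and mean durations follow the dataset statistics of the
#' modelled barn recordings: cough 0.8-3.0 kHz transient bursts (1.82 s),
#' scream 3.0-8.0 kHz sustained high energy (1.75 s), estrus 1.0-3.5 kHz
#' rhythmic pulses (1.94 s), feeding 0.2-2.5 kHz continuous rough texture
#' (1.88 s), normal 0-1.5 kHz ambient (1.80 s).
#'
#' @return named list of five [classProfile()] objects.
#' @export
defaultProfiles <- function() {
  list(
    cough   = classProfile("cough",   c(800, 3000),  c(1.82, 0.12), "transient",
                           eventSnrDb = 18),
    scream  = classProfile("scream",  c(3000, 8000), c(1.75, 0.12), "sustained",
                           eventSnrDb = 20),
    estrus  = classProfile("estrus",  c(1000, 3500), c(1.94, 0.12), "rhythmic",
                           pulseRateHz = 4, eventSnrDb = 15),
    feeding = classProfile("feeding", c(200, 2500),  c(1.88, 0.12), "continuous",
                           eventSnrDb = 12),
    normal  = classProfile("normal",  c(0, 1500),    c(1.80, 0.12), "ambient",
                           eventSnrDb = 6)
  )
}

#' @keywords internal
bandNoise <- function(n, loHz, hiHz, sr) {
  x <- stats::rnorm(n)
  nyq <- sr / 2
  hi <- min(hiHz, nyq * 0.999)
  if (loHz <= 0) {
    bf <- signal::butter(4, hi / nyq, type = "low")
  } else {
    bf <- signal::butter(4, c(loHz, hi) / nyq, type = "pass")
  }
  as.numeric(signal::filtfilt(bf, x))
}

#' @keywords internal
slowNoise <- function(n, cutHz, sr) {
  z <- bandNoise(n, 0, max(cutHz, 2), sr)
  s <- stats::sd(z)
  if (s > 0) z / s else z
}

# Barn background: low-frequency rumble plus mains hum with slow wander.
#' @keywords internal
barnBackground <- function(n, sr) {
  t <- (seq_len(n) - 1) / sr
  rumble <- bandNoise(n, 0, 1200, sr)
  rumble <- rumble / max(stats::sd(rumble), 1e-12)
  hum <- 0.5 * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi)) +
    0.25 * sin(2 * pi * 100 * t + stats::runif(1, 0, 2 * pi))
  wander <- 1 + 0.3 * slowNoise(n, 3, sr)
  bg <- (0.8 * rumble + 0.4 * hum) * wander
  bg / sqrt(mean(bg^2))
}

#' @keywords internal
eventEnvelope <- function(envelope, n, sr, pulseRateHz) {
  t <- (seq_len(n) - 1) / sr
  dur <- n / sr
  switch(envelope,
    transient = {
      nb <- sample(1:3, 1)
      centers <- sort(stats::runif(nb, 0.15 * dur, 0.75 * dur))
      env <- rep(0.03, n)
      for (cc in centers) {
        dt <- t - cc
        env <- env + ifelse(dt >= 0, exp(-dt / 0.06) * (1 - exp(-dt / 0.004)), 0)
      }
      env
    },
    sustained = 0.85 + 0.15 * slowNoise(n, 6, sr),
    rhythmic = {
      period <- 1 / pulseRateHz
      env <- rep(0.05, n)
      k <- 0
      while (k * period < dur) {
        cc <- k * period + stats::runif(1, -0.01, 0.01)
        dt <- abs(t - cc)
        w <- 0.055
        env <- env + ifelse(dt < w, 0.5 * (1 + cos(pi * dt / w)), 0)
        k <- k + 1
      }
      env
    },
    continuous = pmax(0.15, 1 + 0.6 * slowNoise(n, 15, sr)),
    ambient = 1 + 0.2 * slowNoise(n, 4, sr),
    stopInvalid("unknown envelope family: ", envelope)
  )
}

#' Synthesize one vocalization event
#'
#' Deterministic given `(profile, seed)`: band-limited noise shaped by the
#' class envelope family (plus a vibrato harmonic tone for sustained screams
#' and a mid-band tone for rhythmic estrus calls), mixed over a barn
#' background at the profile's event SNR. `bgGainDb` raises the background
#' (used to inject the session-dependent noon shift).
#'
#' @param profile a [classProfile()].
#' @param seed integer seed.
#' @param sr sampling rate in Hz (default 16000).
#' @param bgGainDb extra background gain in dB (default 0).
#' @return a [Waveform-class], peak-normalized to 0.9.
#' @export
synthesizeEvent <- function(profile, seed, sr = 16000, bgGainDb = 0) {
  withLocalSeed(seed, {
    dur <- min(2, max(1, stats::rnorm(1, profile$durationS[1], profile$durationS[2])))
    n <- round(dur * sr)
    base <- bandNoise(n, profile$bandHz[1], profile$bandHz[2], sr)
    base <- base / max(stats::sd(base), 1e-12)
    env <- eventEnvelope(profile$envelope, n, sr, profile$pulseRateHz)
    t <- (seq_len(n) - 1) / sr

    sig <- base * env
    if (profile$envelope == "sustained") {
      f0 <- stats::runif(1, max(profile$bandHz[1], 3100), 3900)
      inst <- f0 * (1 + 0.03 * sin(2 * pi * 5 * t))
      phase <- 2 * pi * cumsum(inst) / sr
      tone <- sin(phase) + 0.3 * sin(2 * phase)
      sig <- (0.5 * base + 0.7 * tone) * env
    } else if (profile$envelope == "rhythmic") {
      f0 <- stats::runif(1, 1400, 2200)
      tone <- sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi))
      sig <- (base + 0.4 * tone) * env
    }

    bg <- barnBackground(n, sr)
    psig <- mean(sig^2)
    pbg <- psig / 10^((profile$eventSnrDb - bgGainDb) / 10)
    out <- sig + bg * sqrt(pbg)
    out <- 0.9 * out / max(abs(out))
    Waveform(out, sr)
  })
}

#' Synthesize a pool of non-event background segments
#'
#' Segments contain barn background (ventilation rumble, mains hum) plus
#' sparse impulsive pen-contact clicks, with no rhythmic pulse structure.
#' Each segment carries a group key `(pen_id, date, session)` drawn from the
#' same universe as [generateDataset()], so group-exclusive noise selection
#' can be enforced during robustness sweeps.
#'
#' @param nSegments number of segments (>= 1).
#' @param seed integer seed.
#' @param sr sampling rate (default 16000).
#' @param durS segment duration in seconds (default 2).
#' @param nPens,nDates group-key universe sizes (defaults match
#'   [generateDataset()]).
#' @return list of `list(wave = Waveform, key = list(pen_id, date, session))`.
#' @export
synthesizeNoisePool <- function(nSegments, seed, sr = 16000, durS = 2,
                                nPens = 5, nDates = 6) {
  stopifnot(nSegments >= 1)
  withLocalSeed(seed, {
    lapply(seq_len(nSegments), function(i) {
      n <- round(durS * sr)
      bg <- barnBackground(n, sr)
      nclicks <- sample(0:4, 1)
      if (nclicks > 0) {
        for (cc in stats::runif(nclicks, 0.05, durS - 0.05)) {
          a <- round(cc * sr)
          len <- round(0.005 * sr)
          bg[a:(a + len)] <- bg[a:(a + len)] +
            stats::runif(1, 1.5, 3) * exp(-(0:len) / (0.001 * sr)) * sign(stats::rnorm(1))
        }
      }
      bg <- 0.9 * bg / max(abs(bg))
      list(
        wave = Waveform(bg, sr),
        key = list(pen_id = paste0("pen", sample.int(nPens, 1)),
                   date = sprintf("d%02d", sample.int(nDates, 1)),
                   session = sample(c("morning", "noon", "evening"), 1))
      )
    })
  })
}

#' Generate a synthetic barn dataset manifest
#'
#' Distributes `nPerClass` clips per class over a restricted pool of active
#' `pen x date x session` groups (so groups contain several correlated
#' samples, as in real recording sessions). Estrus clips live in breeding
#' stalls with their own session-level groups; a `coughCloseFraction` share
#' of cough clips is marked close-range and tied to one of `nPigs`
#' symptomatic pigs. Noon sessions get an elevated background gain,
#' injecting a reproducible midday domain shift.
#'
#' @param nPerClass clips per class (>= 1).
#' @param nPens number of finishing pens (default 5).
#' @param nDates number of recording dates (default 6).
#' @param seed master seed; regeneration is bit-identical.
#' @param profiles list of class profiles (default [defaultProfiles()]).
#' @param coughCloseFraction fraction of cough clips from targeted
#'   close-range recording (default 0.74).
#' @param nPigs number of symptomatic pigs providing close-range coughs
#'   (default 5).
#' @param sessionGainDb named background gains per session in dB
#'   (default `c(morning = 0, noon = 4, evening = 1)`).
#' @param groupsPerClass number of active groups per class (default
#'   `max(6, nPerClass %/% 6)`).
#' @return a [BarnManifest-class].
#' @export
generateDataset <- function(nPerClass, nPens = 5, nDates = 6, seed = 42,
                            profiles = defaultProfiles(),
                            coughCloseFraction = 0.74, nPigs = 5,
                            sessionGainDb = c(morning = 0, noon = 4, evening = 1),
                            groupsPerClass = NULL) {
  stopifnot(nPerClass >= 1, nPens >= 1, nDates >= 1)
  if (!all(c("morning", "noon", "evening") %in% names(sessionGainDb)))
    stopInvalid("sessionGainDb must name morning, noon and evening")
  if (is.null(groupsPerClass)) groupsPerClass <- max(6, nPerClass %/% 6)

  withLocalSeed(seed, {
    sessions <- c("morning", "noon", "evening")
    rows <- list()
    counter <- 0
    for (cls in pigClasses()) {
      pens <- if (cls == "estrus") paste0("stall", 1:3) else paste0("pen", seq_len(nPens))
      combos <- expand.grid(pen_id = pens,
                            date = sprintf("d%02d", seq_len(nDates)),
                            session = sessions, stringsAsFactors = FALSE)
      ng <- min(groupsPerClass, nrow(combos))
      active <- combos[sample.int(nrow(combos), ng), , drop = FALSE]
      grpEffect <- stats::rnorm(ng, 0, 0.3)

      nClose <- if (cls == "cough") round(coughCloseFraction * nPerClass) else 0
      # each symptomatic pig is recorded in one targeted visit, so its
      # close-range clips share a single date and session (pig-wise groups
      # then nest inside sessions, keeping LOSO splits leakage-free)
      pigDate <- sprintf("d%02d", sample.int(nDates, nPigs, replace = TRUE))
      pigSess <- sample(sessions, nPigs, replace = TRUE)
      for (j in seq_len(nPerClass)) {
        counter <- counter + 1
        close <- j <= nClose
        gi <- sample.int(ng, 1)
        pen <- active$pen_id[gi]
        date <- active$date[gi]
        sess <- active$session[gi]
        pig <- NA_character_
        if (close) {
          pi <- 1 + (j - 1) %% nPigs
          pig <- paste0("pig", pi)
          pen <- "obs"
          date <- pigDate[pi]
          sess <- pigSess[pi]
        }
        rows[[counter]] <- data.frame(
          id = sprintf("s%04d", counter), label = cls, pen_id = pen,
          date = date, session = sess, pig_id = pig, close_range = close,
          event_seed = deriveSeed(seed, counter),
          bg_gain_db = sessionGainDb[[sess]] + grpEffect[gi] + stats::rnorm(1, 0, 0.3),
          stringsAsFactors = FALSE
        )
      }
    }
    rec <- do.call(rbind, rows)
    rownames(rec) <- NULL
    new("BarnManifest", records = rec, seed = as.integer(seed),
        config = list(nPerClass = nPerClass, nPens = nPens, nDates = nDates,
                      coughCloseFraction = coughCloseFraction, nPigs = nPigs,
                      sessionGainDb = as.list(sessionGainDb),
                      groupsPerClass = groupsPerClass))
  })
}

#' Regenerate the waveform of one manifest record
#'
#' @param manifest a [BarnManifest-class].
#' @param i record index or id.
#' @param profiles class profiles used at generation time.
#' @return a [Waveform-class].
#' @export
synthRecordWave <- function(manifest, i, profiles = defaultProfiles()) {
  r <- manifestRecords(manifest)
  if (is.character(i)) i <- match(i, r$id)
  row <- r[i, ]
  synthesizeEvent(profiles[[row$label]], row$event_seed, bgGainDb = row$bg_gain_db)
}

#' Mix a noise segment into a signal at a target SNR
#'
#' The noise is tiled/cropped to the signal length and rescaled so that
#' `10 log10(P_signal / P_noise) = snrDb`, then added.
#'
#' @param sig signal [Waveform-class].
#' @param noise noise [Waveform-class] at the same rate.
#' @param snrDb target signal-to-noise ratio in dB.
#' @return mixed [Waveform-class].
#' @export
mixAtSnr <- function(sig, noise, snrDb) {
  stopifnot(is(sig, "Waveform"), is(noise, "Waveform"))
  if (sampleRate(sig) != sampleRate(noise)) stopInvalid("sample rates differ")
  x <- samples(sig)
  nz <- samples(noise)
  if (length(nz) < length(x)) nz <- rep_len(nz, length(x))
  nz <- nz[seq_along(x)]
  psig <- mean(x^2)
  pnz <- mean(nz^2)
  if (psig == 0 || pnz == 0) stopInvalid("zero-power signal or noise")
  scale <- sqrt(psig / (pnz * 10^(snrDb / 10)))
  Waveform(x + scale * nz, sampleRate(sig))
}

#' Write a manifest's clips and metadata to disk
#'
#' Writes one WAV per record, a tab-separated manifest table and a JSON
#' sidecar with the generation config and seed.
#'
#' @param manifest a [BarnManifest-class].
#' @param outDir output directory (created if missing).
#' @param profiles class profiles (default [defaultProfiles()]).
#' @return path of the manifest table, invisibly.
#' @export
materializeDataset <- function(manifest, outDir, profiles = defaultProfiles()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  r <- manifestRecords(manifest)
  paths <- character(nrow(r))
  for (i in seq_len(nrow(r))) {
    paths[i] <- file.path(outDir, paste0(r$id[i], ".wav"))
    writeWav(synthRecordWave(manifest, i, profiles), paths[i])
  }
  tab <- cbind(path = basename(paths), r)
  tabPath <- file.path(outDir, "manifest.tsv")
  utils::write.table(tab, tabPath, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = manifestSeed(manifest), config = manifest@config),
    file.path(outDir, "generation-config.json"), auto_unbox = TRUE, digits = NA)
  invisible(tabPath)
}

#' Read a materialized manifest table back into a BarnManifest
#'
#' @param path path to a `manifest.tsv` written by [materializeDataset()].
#' @return a [BarnManifest-class] (the `path` column is dropped).
#' @export
readManifest <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  cfgPath <- file.path(dirname(path), "generation-config.json")
  cfg <- if (file.exists(cfgPath)) jsonlite::read_json(cfgPath) else list()
  tab$path <- NULL
  tab$pig_id <- as.character(tab$pig_id)
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 0L
  new("BarnManifest", records = tab, seed = seed,
      config = if (is.null(cfg$config)) list() else cfg$config)
}
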