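#' @import methods
NULL

#' Mono waveform container
#'
#' Holds a single-channel amplitude sequence together with its sampling rate.
#' All front-end operations consume and produce `Waveform` objects; the
#' canonical working format is 16 kHz mono with peak amplitude at most 1.
#'
#' @slot samples numeric vector of amplitudes (dimensionless).
#' @slot sampleRate sampling rate in Hz.
#' @export
setClass("Waveform",
  representation(samples = "numeric", sampleRate = "numeric"),
  validity = function(object) {
    if (length(object@samples) < 1) return("waveform must contain at least one sample")
    if (!all(is.finite(object@samples))) return("waveform samples must be finite")
    if (length(object@sampleRate) != 1 || object@sampleRate <= 0)
      return("sampleRate must be a single positive number")
    TRUE
  }
)

#' Construct a Waveform
#'
#' @param samples numeric amplitude vector (mono).
#' @param sampleRate sampling rate in Hz.
#' @return a [Waveform-class] object.
#' @examples
#' w <- Waveform(sin(2 * pi * 440 * seq(0, 1, length.out = 16000)), 16000)
#' sampleRate(w)
#' @export
Waveform <- function(samples, sampleRate) {
  new("Waveform", samples = as.numeric(samples), sampleRate = as.numeric(sampleRate))
}

#' Log-mel spectrogram container
#'
#' An F x T matrix of log mel-filterbank energies (natural log of power with
#' an additive floor), plus the framing parameters that produced it.
#'
#' @slot values numeric matrix, `n_mels` rows by T frame columns.
#' @slot sampleRate source sampling rate in Hz.
#' @slot frameLenMs analysis window length in milliseconds.
#' @slot hopMs hop between frames in milliseconds.
#' @slot fminHz lower edge of the mel filterbank in Hz.
#' @slot fmaxHz upper edge of the mel filterbank in Hz.
#' @export
setClass("MelSpectrogram",
  representation(values = "matrix", sampleRate = "numeric",
                 frameLenMs = "numeric", hopMs = "numeric",
                 fminHz = "numeric", fmaxHz = "numeric"),
  validity = function(object) {
    if (nrow(object@values) < 1 || ncol(object@values) < 1)
      return("spectrogram must have at least one mel bin and one frame")
    if (!all(is.finite(object@values))) return("spectrogram values must be finite")
    if (object@fminHz < 0 || object@fmaxHz <= object@fminHz)
      return("need 0 <= fminHz < fmaxHz")
    TRUE
  }
)

#' @keywords internal
newMelSpectrogram <- function(values, sampleRate = 16000, frameLenMs = 25,
                              hopMs = 10, fminHz = 0, fmaxHz = 8000) {
  new("MelSpectrogram", values = values, sampleRate = sampleRate,
      frameLenMs = frameLenMs, hopMs = hopMs, fminHz = fminHz, fmaxHz = fmaxHz)
}

#' Frame validity mask
#'
#' Binary per-frame validity bits; 0 marks silent or otherwise suppressed
#' frames that masked attentive pooling must ignore.
#'
#' @slot bits integer vector of 0/1 values, one per frame.
#' @export
setClass("FrameMask",
  representation(bits = "integer"),
  validity = function(object) {
    if (length(object@bits) < 1) return("mask must have at least one frame")
    if (!all(object@bits %in% c(0L, 1L))) return("mask bits must be 0 or 1")
    TRUE
  }
)

#' Construct a FrameMask
#' @param bits vector coercible to 0/1 integers.
#' @return a [FrameMask-class] object.
#' @export
FrameMask <- function(bits) new("FrameMask", bits = as.integer(bits))

#' Synthetic barn dataset manifest
#'
#' One row per clip: label, group metadata (pen, date, session), optional pig
#' identity for close-range cough recordings, the per-record synthesis seed and
#' the session-dependent background gain. Regeneration from `(seed, config)` is
#' bit-identical.
#'
#' @slot records data.frame with columns `id`, `label`, `pen_id`, `date`,
#'   `session`, `pig_id`, `close_range`, `event_seed`, `bg_gain_db`.
#' @slot seed integer master seed the manifest was generated from.
#' @slot config list of generator settings.
#' @export
setClass("BarnManifest",
  representation(records = "data.frame", seed = "integer", config = "list"),
  validity = function(object) {
    r <- object@records
    need <- c("id", "label", "pen_id", "date", "session", "pig_id",
              "close_range", "event_seed", "bg_gain_db")
    if (!all(need %in% names(r)))
      return(paste("manifest records missing columns:",
                   paste(setdiff(need, names(r)), collapse = ", ")))
    if (!all(r$label %in% pigClasses())) return("labels must be one of the five classes")
    if (!all(r$session %in% c("morning", "noon", "evening")))
      return("session must be morning/noon/evening")
    if (any(r$close_range & is.na(r$pig_id)))
      return("close-range records must carry a pig_id")
    if (anyDuplicated(r$id)) return("record ids must be unique")
    TRUE
  }
)

setMethod("show", "Waveform", function(object) {
  cat(sprintf("Waveform: %d samples @ %g Hz (%.3f s), peak %.3g\n",
              length(object@samples), object@sampleRate,
              length(object@samples) / object@sampleRate,
              max(abs(object@samples))))
})

setMethod("show", "MelSpectrogram", function(object) {
  cat(sprintf("MelSpectrogram: %d mel bins x %d frames (%g ms window, %g ms hop, %g-%g Hz)\n",
              nrow(object@values), ncol(object@values), object@frameLenMs,
              object@hopMs, object@fminHz, object@fmaxHz))
})

setMethod("show", "FrameMask", function(object) {
  cat(sprintf("FrameMask: %d frames, %d valid\n",
              length(object@bits), sum(object@bits)))
})

setMethod("show", "BarnManifest", function(object) {
  r <- object@records
  cat(sprintf("BarnManifest: %d records, seed %d\n", nrow(r), object@seed))
  print(table(r$label))
})

#' @rdname Waveform-class
#' @param x,object a SwineVox object.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname Waveform-class
#' @export
setMethod("samples", "Waveform", function(x) x@samples)

#' @rdname Waveform-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname Waveform-class
#' @export
setMethod("sampleRate", "Waveform", function(x) x@sampleRate)
#' @rdname MelSpectrogram-class
#' @export
setMethod("sampleRate", "MelSpectrogram", function(x) x@sampleRate)

#' @rdname MelSpectrogram-class
#' @param x a `MelSpectrogram`.
#' @export
setGeneric("melValues", function(x) standardGeneric("melValues"))
#' @rdname MelSpectrogram-class
#' @export
setMethod("melValues", "MelSpectrogram", function(x) x@values)

#' @rdname MelSpectrogram-class
#' @export
setGeneric("nMels", function(x) standardGeneric("nMels"))
#' @rdname MelSpectrogram-class
#' @export
setMethod("nMels", "MelSpectrogram", function(x) nrow(x@values))

#' @rdname MelSpectrogram-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname MelSpectrogram-class
#' @export
setMethod("nFrames", "MelSpectrogram", function(x) ncol(x@values))
#' @rdname FrameMask-class
#' @export
setMethod("nFrames", "FrameMask", function(x) length(x@bits))

#' @rdname FrameMask-class
#' @param x a `FrameMask`.
#' @export
setGeneric("maskBits", function(x) standardGeneric("maskBits"))
#' @rdname FrameMask-class
#' @export
setMethod("maskBits", "FrameMask", function(x) x@bits)

#' @rdname BarnManifest-class
#' @param x a `BarnManifest`.
#' @export
setGeneric("manifestRecords", function(x) standardGeneric("manifestRecords"))
#' @rdname BarnManifest-class
#' @export
setMethod("manifestRecords", "BarnManifest", function(x) x@records)

#' @rdname BarnManifest-class
#' @export
setGeneric("manifestSeed", function(x) standardGeneric("manifestSeed"))
#' @rdname BarnManifest-class
#' @export
setMethod("manifestSeed", "BarnManifest", function(x) x@seed)
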