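#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF reader for the uncompressed PCM clips this package works with.
#' Multi-channel files are refused; only 16-bit PCM is supported.
#'
#' @param path path to a `.wav` file.
#' @return a [Waveform-class] with samples scaled to `[-1, 1]`.
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopInvalid("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopInvalid("not a WAVE file: ", path)

  fmt <- NULL
  data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        format   = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate     = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data <- readBin(con, "integer", sz / 2, 2, signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
  }
  if (is.null(fmt) || is.null(data)) stopInvalid("missing fmt/data chunk in ", path)
  if (fmt$format != 1 || fmt$bits != 16) stopInvalid("only 16-bit PCM WAV supported")
  if (fmt$channels != 1) stopInvalid("only mono WAV supported")
  Waveform(data / 32768, fmt$rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' Samples are clipped to `[-1, 1]` and quantized to 16 bits.
#'
#' @param w a [Waveform-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeWav <- function(w, path) {
  stopifnot(is(w, "Waveform"))
  x <- pmax(-1, pmin(1, samples(w)))
  pcm <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, 2, endian = "little")        # PCM, mono
  writeBin(as.integer(sampleRate(w)), con, 4, endian = "little")
  writeBin(as.integer(sampleRate(w) * 2), con, 4, endian = "little") # byte rate
  writeBin(as.integer(c(2, 16)), con, 2, endian = "little")       # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
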