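#' Read labelled intervals from a Praat TextGrid tier
#'
#' Parses a long-format Praat TextGrid and returns the non-empty labelled
#' intervals of one interval tier, as produced by manual annotation of long
#' barn recordings. Empty labels are skipped.
#'
#' @param path path to a long-format `.TextGrid` file.
#' @param tierName name of the interval tier to read.
#' @return data.frame with columns `label`, `start_s`, `end_s`, `tier`.
#' @export
readTextGridSegments <- function(path, tierName) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("ooTextFile", lines))) stopInvalid("not a Praat TextGrid: ", path)
  txt <- trimws(lines)

  getNum <- function(s) as.numeric(sub('.*= *', '', s))
  getStr <- function(s) {
    m <- regmatches(s, regexpr('"[^"]*"', s))
    if (length(m) == 0) "" else substr(m, 2, nchar(m) - 1)
  }

  item_starts <- grep("^item *\\[[0-9]+\\]:", txt)
  if (length(item_starts) == 0) stopInvalid("no tiers found in ", path)
  item_ends <- c(item_starts[-1] - 1, length(txt))

  for (i in seq_along(item_starts)) {
    block <- txt[item_starts[i]:item_ends[i]]
    cls <- getStr(block[grep("^class *=", block)[1]])
    nm <- getStr(block[grep("^name *=", block)[1]])
    if (!identical(nm, tierName)) next
    if (!identical(cls, "IntervalTier"))
      stopInvalid("tier '", tierName, "' is not an IntervalTier")
    iv_starts <- grep("^intervals *\\[[0-9]+\\]:", block)
    out <- list()
    for (j in seq_along(iv_starts)) {
      from <- iv_starts[j]
      to <- if (j < length(iv_starts)) iv_starts[j + 1] - 1 else length(block)
      sub <- block[from:to]
      xmin <- getNum(sub[grep("^xmin *=", sub)[1]])
      xmax <- getNum(sub[grep("^xmax *=", sub)[1]])
      lab <- getStr(sub[grep("^text *=", sub)[1]])
      if (nzchar(lab)) out[[length(out) + 1]] <-
          data.frame(label = lab, start_s = xmin, end_s = xmax,
                     tier = tierName, stringsAsFactors = FALSE)
    }
    if (length(out) == 0)
      return(data.frame(label = character(), start_s = numeric(),
                        end_s = numeric(), tier = character(),
                        stringsAsFactors = FALSE))
    return(do.call(rbind, out))
  }
  stopInvalid("tier '", tierName, "' not found in ", path)
}

#' Write a single-tier long-format Praat TextGrid
#'
#' Companion writer used for fixtures and round-trip checks. Gaps between the
#' provided intervals are filled with empty-label intervals so the tier tiles
#' `[0, xmax]` as Praat requires.
#'
#' @param segments data.frame with columns `label`, `start_s`, `end_s`.
#' @param path output path.
#' @param tierName tier name to write.
#' @param xmax total duration of the annotated file (defaults to the last end).
#' @return `path`, invisibly.
#' @export
writeTextGrid <- function(segments, path, tierName = "events", xmax = NULL) {
  seg <- segments[order(segments$start_s), , drop = FALSE]
  if (any(seg$start_s < 0) || any(seg$end_s <= seg$start_s))
    stopInvalid("segments need 0 <= start_s < end_s")
  if (is.null(xmax)) xmax <- if (nrow(seg)) max(seg$end_s) else 1

  # tile [0, xmax] with empty gap intervals
  iv <- list()
  cursor <- 0
  for (i in seq_len(nrow(seg))) {
    if (seg$start_s[i] > cursor + 1e-12)
      iv[[length(iv) + 1]] <- c(cursor, seg$start_s[i], "")
    iv[[length(iv) + 1]] <- c(seg$start_s[i], seg$end_s[i], seg$label[i])
    cursor <- seg$end_s[i]
  }
  if (cursor < xmax - 1e-12) iv[[length(iv) + 1]] <- c(cursor, xmax, "")
  if (length(iv) == 0) iv[[1]] <- c(0, xmax, "")

  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('File type = "ooTextFile"')
  w('Object class = "TextGrid"')
  w('')
  w('xmin = 0')
  w('xmax = %.10g', xmax)
  w('tiers? <exists>')
  w('size = 1')
  w('item []:')
  w('    item [1]:')
  w('        class = "IntervalTier"')
  w('        name = "%s"', tierName)
  w('        xmin = 0')
  w('        xmax = %.10g', xmax)
  w('        intervals: size = %d', length(iv))
  for (i in seq_along(iv)) {
    w('        intervals [%d]:', i)
    w('            xmin = %.10g', as.numeric(iv[[i]][1]))
    w('            xmax = %.10g', as.numeric(iv[[i]][2]))
    w('            text = "%s"', iv[[i]][3])
  }
  invisible(path)
}

#' Cut annotated segments out of a long waveform
#'
#' @param w a [Waveform-class] covering the annotated recording.
#' @param segments data.frame from [readTextGridSegments()].
#' @return list of [Waveform-class] clips, one per annotation row.
#' @export
extractSegments <- function(w, segments) {
  sr <- sampleRate(w)
  x <- samples(w)
  lapply(seq_len(nrow(segments)), function(i) {
    a <- max(1L, floor(segments$start_s[i] * sr) + 1L)
    b <- min(length(x), ceiling(segments$end_s[i] * sr))
    if (b < a) stopInvalid("segment ", i, " lies outside the waveform")
    Waveform(x[a:b], sr)
  })
}
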