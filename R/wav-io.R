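# Minimal RIFF/WAVE PCM I/O. Supports the formats produced by field
# recorders used for passive acoustic monitoring: integer PCM, 16 or
# 24 bit, mono or stereo, arbitrary sampling rate.

#' Read a PCM WAV file
#'
#' Reads 16- or 24-bit integer PCM WAV audio. Samples are rescaled to
#' `[-1, 1]`; stereo recordings are downmixed to mono by averaging the two
#' channels.
#'
#' @param path path to a `.wav` file.
#' @return list with `wave` (numeric vector in `[-1, 1]`), `sampleRate`
#'   (Hz), and `bitDepth`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".wav")
#' writeWav(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), 8000, f)
#' w <- readWav(f)
#' w$sampleRate
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  dataRaw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audioFormat   = readBin(con, "integer", 1, 2, endian = "little"),
        nChannels     = readBin(con, "integer", 1, 2, endian = "little"),
        sampleRate    = readBin(con, "integer", 1, 4, endian = "little"),
        byteRate      = readBin(con, "integer", 1, 4, endian = "little"),
        blockAlign    = readBin(con, "integer", 1, 2, endian = "little"),
        bitsPerSample = readBin(con, "integer", 1, 2, endian = "little")
      )
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      dataRaw <- readBin(con, "raw", size)
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(fmt)) stop("no fmt chunk found in ", path)
  if (is.null(dataRaw)) stop("no data chunk found in ", path)
  if (fmt$audioFormat != 1)
    stop("only integer PCM WAV is supported (format tag ", fmt$audioFormat, ")")
  bits <- fmt$bitsPerSample
  if (!bits %in% c(16L, 24L))
    stop("only 16- or 24-bit PCM is supported, got ", bits, " bits")

  if (bits == 16L) {
    x <- readBin(dataRaw, "integer", length(dataRaw) %/% 2, 2,
                 signed = TRUE, endian = "little")
    x <- x / 32768
  } else {
    n <- length(dataRaw) %/% 3
    b <- matrix(as.integer(dataRaw[seq_len(3 * n)]), nrow = 3)
    x <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    x <- ifelse(x >= 8388608, x - 16777216, x) / 8388608
  }
  if (fmt$nChannels == 2L) {
    x <- (x[c(TRUE, FALSE)] + x[c(FALSE, TRUE)]) / 2
  } else if (fmt$nChannels != 1L) {
    stop("unsupported channel count: ", fmt$nChannels)
  }
  list(wave = x, sampleRate = fmt$sampleRate, bitDepth = bits)
}

#' Write a PCM WAV file
#'
#' @param wave numeric vector of samples in `[-1, 1]` (values are clipped),
#'   or a two-column matrix for stereo.
#' @param sampleRate sampling rate in Hz.
#' @param path output path.
#' @param bitDepth 16 (default) or 24.
#' @return `path`, invisibly.
#' @export
writeWav <- function(wave, sampleRate, path, bitDepth = 16) {
  stopifnot(sampleRate > 0, bitDepth %in% c(16, 24))
  if (is.matrix(wave)) {
    nch <- ncol(wave)
    x <- as.numeric(t(wave))  # interleave
  } else {
    nch <- 1L
    x <- as.numeric(wave)
  }
  x <- pmin(pmax(x, -1), 1)
  bytesPer <- bitDepth %/% 8
  dataSize <- length(x) * bytesPer
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(nch), con, 2, endian = "little")
  writeBin(as.integer(sampleRate), con, 4, endian = "little")
  writeBin(as.integer(sampleRate * nch * bytesPer), con, 4, endian = "little")
  writeBin(as.integer(nch * bytesPer), con, 2, endian = "little")
  writeBin(as.integer(bitDepth), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, 4, endian = "little")
  if (bitDepth == 16) {
    writeBin(as.integer(round(x * 32767)), con, 2, endian = "little")
  } else {
    v <- as.integer(round(x * 8388607))
    v <- ifelse(v < 0, v + 16777216L, v)
    b <- rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}
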