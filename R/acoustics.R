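# Acoustic Complexity Index stage: STFT power spectrogram -> band limit ->
# ACI per fixed time window -> hourly aggregation.

#' Short-time power spectrogram of an audio waveform
#'
#' Computes squared STFT magnitudes on a frequency x time grid via
#' [signal::specgram()]. The number of frames is
#' `floor((n - frameLength) / hop) + 1`; frequency bands are the one-sided
#' FFT bins, each of width `sampleRate / frameLength`.
#'
#' @param wave numeric vector of audio samples, or a two-column matrix
#'   (stereo, downmixed by averaging).
#' @param sampleRate sampling rate in Hz (> 0).
#' @param frameLength STFT frame length in samples (>= 2); default 1024.
#' @param hop hop between frame starts in samples; default 512.
#' @param window analysis window: `"hann"` (default) or `"rectangular"`.
#' @param startTime `POSIXct` timestamp of the first sample.
#' @return a [PowerSpectrogram-class] object.
#' @export
#' @examples
#' ps <- computeSpectrogram(rnorm(48000), 48000)
#' nFrames(ps)  # floor((48000 - 1024) / 512) + 1 = 92
computeSpectrogram <- function(wave, sampleRate,
                               frameLength = 1024, hop = 512,
                               window = c("hann", "rectangular"),
                               startTime = simEpoch()) {
  if (is.matrix(wave) && ncol(wave) == 2) wave <- rowMeans(wave)
  wave <- as.numeric(wave)
  if (length(wave) == 0) stop("empty audio")
  if (sampleRate <= 0) stop("sampleRate must be positive")
  stopifnot(frameLength >= 2, hop >= 1)
  if (length(wave) < frameLength)
    stop("audio shorter than one analysis frame (", frameLength, " samples)")
  window <- match.arg(window)
  win <- if (window == "hann") signal::hanning(frameLength)
         else rep(1, frameLength)
  sp <- signal::specgram(wave, n = frameLength, Fs = sampleRate,
                         window = win, overlap = frameLength - hop)
  pow <- Mod(sp$S)^2
  binWidth <- sampleRate / frameLength
  PowerSpectrogram(pow,
                   freqLower = as.numeric(sp$f),
                   freqUpper = as.numeric(sp$f) + binWidth,
                   timeStep = hop / sampleRate,
                   startTime = startTime)
}

#' Restrict a spectrogram to a frequency band
#'
#' Keeps the frequency rows whose band overlaps `[fMin, fMax]`, preserving
#' row order. The default band, 0-24 kHz, covers the focal species' vocal
#' range.
#'
#' @param spec a [PowerSpectrogram-class].
#' @param fMin,fMax band edges in Hz, `fMin < fMax`.
#' @return a band-limited [PowerSpectrogram-class].
#' @export
setGeneric("bandLimit", function(spec, fMin = 0, fMax = 24000)
  standardGeneric("bandLimit"))

#' @rdname bandLimit
#' @export
setMethod("bandLimit", "PowerSpectrogram", function(spec, fMin = 0,
                                                    fMax = 24000) {
  if (!(fMin < fMax)) stop("fMin must be smaller than fMax")
  keep <- spec@freqUpper > fMin & spec@freqLower < fMax
  if (!any(keep)) stop("empty band: no frequency rows overlap [",
                       fMin, ", ", fMax, "] Hz")
  PowerSpectrogram(spec@power[keep, , drop = FALSE],
                   freqLower = spec@freqLower[keep],
                   freqUpper = spec@freqUpper[keep],
                   timeStep = spec@timeStep,
                   startTime = spec@startTime)
})

#' Acoustic Complexity Index of a spectrogram window
#'
#' Sums, over every frequency band and every pair of adjacent time frames,
#' the normalized absolute intensity change
#' \deqn{ACI = \sum_f \sum_i \frac{|P(f, t_i) - P(f, t_{i-1})|}
#'                                {P(f, t_i) + P(f, t_{i-1})}.}
#' A pair whose power sum is zero (silence in that band) contributes 0, so
#' silent bands never change the index. Each summand lies in `[0, 1]`,
#' hence `0 <= ACI <= nBands * (nFrames - 1)`, and the index is invariant
#' to rescaling all power values by a positive constant.
#'
#' `normalization = "total"` instead divides each band's summed absolute
#' differences by that band's total power over the window (the classical
#' soundscape-ecology normalization), provided for comparison.
#'
#' @param spec a [PowerSpectrogram-class] or a nonnegative numeric matrix
#'   (rows = frequency bands, columns = time frames).
#' @param normalization `"pairwise"` (default) or `"total"`.
#' @return a single nonnegative number.
#' @export
#' @examples
#' aciValue(matrix(c(1, 3, 1, 3), nrow = 1))  # 3 * |2|/4 = 1.5
setGeneric("aciValue", function(spec, normalization = c("pairwise", "total"))
  standardGeneric("aciValue"))

#' @rdname aciValue
#' @export
setMethod("aciValue", "matrix", function(spec,
                                         normalization = c("pairwise",
                                                           "total")) {
  normalization <- match.arg(normalization)
  if (ncol(spec) < 2) stop("window too short: need at least 2 time frames")
  if (any(spec < 0)) stop("power values must be nonnegative")
  d <- abs(spec[, -1, drop = FALSE] - spec[, -ncol(spec), drop = FALSE])
  if (normalization == "pairwise") {
    s <- spec[, -1, drop = FALSE] + spec[, -ncol(spec), drop = FALSE]
    ratio <- d / s
    ratio[s == 0] <- 0
    sum(ratio)
  } else {
    tot <- rowSums(spec)
    perBand <- rowSums(d) / tot
    perBand[tot == 0] <- 0
    sum(perBand)
  }
})

#' @rdname aciValue
#' @export
setMethod("aciValue", "PowerSpectrogram",
          function(spec, normalization = c("pairwise", "total")) {
  aciValue(spec@power, normalization = match.arg(normalization))
})

#' ACI in consecutive fixed-length time windows
#'
#' Partitions the spectrogram into consecutive non-overlapping windows of
#' `windowS` seconds (default 600 s), computes [aciValue()] in each, and
#' also returns the total over windows (the whole-recording ACI). A
#' trailing partial window is kept if it still spans at least two frames,
#' otherwise dropped.
#'
#' @param spec a [PowerSpectrogram-class].
#' @param windowS window length in seconds; must exceed twice the frame
#'   step.
#' @param normalization passed to [aciValue()].
#' @return list with `windows` (data.frame: `window_index`, `start_time`,
#'   `aci`) and `total` (sum over windows).
#' @export
setGeneric("aciWindows", function(spec, windowS = 600,
                                  normalization = c("pairwise", "total"))
  standardGeneric("aciWindows"))

#' @rdname aciWindows
#' @export
setMethod("aciWindows", "PowerSpectrogram",
          function(spec, windowS = 600,
                   normalization = c("pairwise", "total")) {
  normalization <- match.arg(normalization)
  if (windowS <= 2 * spec@timeStep)
    stop("windowS must exceed twice the frame step (",
         signif(2 * spec@timeStep, 4), " s)")
  cpw <- max(2L, as.integer(round(windowS / spec@timeStep)))
  nc <- ncol(spec@power)
  starts <- seq(1L, nc, by = cpw)
  keep <- (pmin(starts + cpw - 1L, nc) - starts + 1L) >= 2L
  starts <- starts[keep]
  if (length(starts) == 0)
    stop("window too short: spectrogram has fewer than 2 frames per window")
  aci <- vapply(starts, function(s0) {
    aciValue(spec@power[, s0:min(s0 + cpw - 1L, nc), drop = FALSE],
             normalization = normalization)
  }, numeric(1))
  win <- data.frame(
    window_index = seq_along(starts),
    start_time = spec@startTime + (starts - 1L) * spec@timeStep,
    aci = aci
  )
  list(windows = win, total = sum(aci))
})

#' Aggregate window ACI values to an hourly series
#'
#' Windows are assigned to the clock hour of their start time; the hourly
#' ACI is the arithmetic mean of member windows. Hours are returned in
#' night order (from `nightStart` onward, wrapping midnight), then any
#' remaining hours.
#'
#' @param windows the `windows` data.frame from [aciWindows()] (columns
#'   `start_time`, `aci`), or the list returned by [aciWindows()].
#' @param nightStart clock hour anchoring the output order (default 17).
#' @return data.frame with `hour`, `aci` (mean), `n_windows`.
#' @export
hourlyAci <- function(windows, nightStart = 17) {
  if (is.list(windows) && !is.data.frame(windows) &&
      !is.null(windows$windows)) windows <- windows$windows
  if (nrow(windows) == 0)
    return(data.frame(hour = integer(), aci = numeric(),
                      n_windows = integer()))
  hour <- hourOf(windows$start_time)
  agg <- aggregate(windows$aci, list(hour = hour),
                   function(v) c(mean(v), length(v)))
  out <- data.frame(hour = agg$hour,
                    aci = agg$x[, 1],
                    n_windows = as.integer(agg$x[, 2]))
  out[order((out$hour - nightStart) %% 24), , drop = FALSE]
}

#' Hourly ACI profile of a simulated night
#'
#' Convenience wrapper for the output of [genNightAudio()]: computes a
#' band-limited spectrogram for each hourly audio segment, the ACI in
#' fixed windows, and the hourly mean series.
#'
#' @param night a list as returned by [genNightAudio()] (elements
#'   `segments`, `sampleRate`, and segment names giving the clock hour).
#' @param frameLength,hop,window STFT parameters, see
#'   [computeSpectrogram()].
#' @param fMin,fMax analysis band in Hz, see [bandLimit()].
#' @param windowS ACI window length in seconds (default 10 s, matched to
#'   the short duty-cycle segments the generator produces).
#' @return data.frame with `hour`, `aci`, `n_windows` in night order.
#' @export
hourlyAciOfNight <- function(night, frameLength = 256, hop = 128,
                             window = "hann", fMin = 0, fMax = 24000,
                             windowS = 10) {
  stopifnot(is.list(night), !is.null(night$segments),
            !is.null(night$sampleRate))
  hours <- as.integer(names(night$segments))
  base <- if (!is.null(night$date)) night$date else simEpoch()
  win <- lapply(seq_along(hours), function(i) {
    h <- hours[i]
    st <- base + h * 3600
    ps <- computeSpectrogram(night$segments[[i]], night$sampleRate,
                             frameLength = frameLength, hop = hop,
                             window = window, startTime = st)
    ps <- bandLimit(ps, fMin, fMax)
    aciWindows(ps, windowS = windowS)$windows
  })
  hourlyAci(do.call(rbind, win))
}
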