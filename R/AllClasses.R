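#' PowerSpectrogram: spectral power on a frequency x time grid
#'
#' S4 container for a short-time power spectrogram: nonnegative relative
#' power values \eqn{P(f, t_i)} on a grid of frequency bands (rows) and
#' time frames (columns). This is the substrate of the Acoustic Complexity
#' Index: all ACI computations ([aciValue()], [aciWindows()]) operate on
#' objects of this class (or on bare matrices for quick experiments).
#'
#' @slot power numeric matrix of nonnegative spectral power values, one row
#'   per frequency band, one column per time frame.
#' @slot freqLower,freqUpper numeric vectors of band edges in Hz; bands are
#'   strictly increasing and non-overlapping.
#' @slot timeStep seconds between consecutive frame starts (the STFT hop).
#' @slot startTime `POSIXct` timestamp of the first frame.
#'
#' @seealso [computeSpectrogram()] to build one from audio, [bandLimit()]
#'   to restrict the frequency range.
#' @name PowerSpectrogram-class
#' @rdname PowerSpectrogram-class
#' @exportClass PowerSpectrogram
setClass(
  "PowerSpectrogram",
  slots = c(
    power     = "matrix",
    freqLower = "numeric",
    freqUpper = "numeric",
    timeStep  = "numeric",
    startTime = "POSIXct"
  )
)

setValidity("PowerSpectrogram", function(object) {
  msg <- character()
  p <- object@power
  if (!is.numeric(p)) msg <- c(msg, "power must be a numeric matrix")
  else if (any(!is.finite(p))) msg <- c(msg, "power contains non-finite values")
  else if (any(p < 0)) msg <- c(msg, "power values must be nonnegative")
  nf <- length(object@freqLower)
  if (length(object@freqUpper) != nf)
    msg <- c(msg, "freqLower and freqUpper differ in length")
  if (nrow(p) != nf)
    msg <- c(msg, "number of power rows must match number of frequency bands")
  if (nf > 0) {
    if (any(object@freqUpper <= object@freqLower))
      msg <- c(msg, "each band needs freqUpper > freqLower")
    if (nf > 1 && any(diff(object@freqLower) <= 0))
      msg <- c(msg, "frequency bands must be strictly increasing")
    if (nf > 1 &&
        any(object@freqLower[-1] < object@freqUpper[-nf] - 1e-9))
      msg <- c(msg, "frequency bands must not overlap")
  }
  if (length(object@timeStep) != 1 || object@timeStep <= 0)
    msg <- c(msg, "timeStep must be a single positive number")
  if (length(object@startTime) != 1)
    msg <- c(msg, "startTime must have length 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PowerSpectrogram
#'
#' @param power nonnegative numeric matrix (frequency bands x time frames).
#' @param freqLower,freqUpper band edges in Hz. Defaults index bands as
#'   unit-width pseudo-frequencies, convenient for synthetic matrices.
#' @param timeStep seconds per frame hop.
#' @param startTime `POSIXct` timestamp of the first frame.
#' @return a [PowerSpectrogram-class] object.
#' @export
#' @examples
#' ps <- PowerSpectrogram(matrix(runif(40), 4, 10), timeStep = 0.5)
#' nBands(ps); nFrames(ps)
PowerSpectrogram <- function(power,
                             freqLower = seq_len(nrow(power)) - 1,
                             freqUpper = freqLower + 1,
                             timeStep = 1,
                             startTime = simEpoch()) {
  new("PowerSpectrogram",
      power = as.matrix(power),
      freqLower = as.numeric(freqLower),
      freqUpper = as.numeric(freqUpper),
      timeStep = as.numeric(timeStep),
      startTime = as.POSIXct(startTime, tz = "UTC"))
}

#' @describeIn PowerSpectrogram-class the power matrix.
#' @param x,object a `PowerSpectrogram`.
#' @export
setGeneric("specPower", function(x) standardGeneric("specPower"))

#' @rdname PowerSpectrogram-class
#' @export
setMethod("specPower", "PowerSpectrogram", function(x) x@power)

#' @describeIn PowerSpectrogram-class two-column matrix of band edges (Hz).
#' @export
setGeneric("freqBins", function(x) standardGeneric("freqBins"))

#' @rdname PowerSpectrogram-class
#' @export
setMethod("freqBins", "PowerSpectrogram", function(x)
  cbind(lower = x@freqLower, upper = x@freqUpper))

#' @describeIn PowerSpectrogram-class seconds per frame hop.
#' @export
setGeneric("timeStep", function(x) standardGeneric("timeStep"))

#' @rdname PowerSpectrogram-class
#' @export
setMethod("timeStep", "PowerSpectrogram", function(x) x@timeStep)

#' @describeIn PowerSpectrogram-class timestamp of the first frame.
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))

#' @rdname PowerSpectrogram-class
#' @export
setMethod("startTime", "PowerSpectrogram", function(x) x@startTime)

#' @describeIn PowerSpectrogram-class number of frequency bands (rows).
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname PowerSpectrogram-class
#' @export
setMethod("nBands", "PowerSpectrogram", function(x) nrow(x@power))

#' @describeIn PowerSpectrogram-class number of time frames (columns).
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname PowerSpectrogram-class
#' @export
setMethod("nFrames", "PowerSpectrogram", function(x) ncol(x@power))

setMethod("show", "PowerSpectrogram", function(object) {
  fr <- range(object@freqLower, object@freqUpper)
  cat("PowerSpectrogram:", nrow(object@power), "bands x",
      ncol(object@power), "frames\n")
  cat(sprintf("  frequency range: %.0f-%.0f Hz\n", fr[1], fr[2]))
  cat(sprintf("  time step: %.6g s, duration: %.4g s\n",
              object@timeStep, object@timeStep * ncol(object@power)))
  cat("  start:", format(object@startTime, "%Y-%m-%d %H:%M:%S %Z"), "\n")
})
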