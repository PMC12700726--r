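# Shared helpers: night-hour arithmetic and reproducible local RNG.

#' Clock hours of the night window, in night order
#'
#' Returns the sequence of clock hours covered by a night window that may
#' wrap midnight, e.g. 17:00-06:00 gives 17, 18, ..., 23, 0, ..., 5. The
#' end hour is exclusive (a window ending at 06:00 contains hour 5 but not
#' hour 6).
#'
#' @param nightStart first clock hour of the window (default 17).
#' @param nightEnd exclusive end clock hour (default 6).
#' @return integer vector of clock hours in night order.
#' @export
#' @examples
#' nightHourSeq()        # 17 18 ... 23 0 ... 5
#' nightHourSeq(20, 2)   # 20 21 22 23 0 1
nightHourSeq <- function(nightStart = 17, nightEnd = 6) {
  stopifnot(nightStart %in% 0:23, nightEnd %in% 0:23)
  if (nightStart == nightEnd)
    stop("night window is empty: nightStart equals nightEnd")
  n <- (nightEnd - nightStart) %% 24
  (nightStart + seq_len(n) - 1L) %% 24L
}

# Clock hour (0-23) of a POSIXct/numeric timestamp, UTC.
hourOf <- function(time) {
  if (inherits(time, "POSIXt")) as.POSIXlt(time, tz = "UTC")$hour
  else (floor(as.numeric(time) / 3600)) %% 24
}

# Position of clock hour within the night order (0-based); NA outside window.
nightIndex <- function(hour, nightStart = 17, nightEnd = 6) {
  idx <- (hour - nightStart) %% 24
  len <- (nightEnd - nightStart) %% 24
  idx[idx >= len] <- NA_integer_
  idx
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Canonical base timestamp used when synthetic data need absolute times.
simEpoch <- function() as.POSIXct("2023-11-01 00:00:00", tz = "UTC")
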