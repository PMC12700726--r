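# Vocal-event stage: merge raw call timestamps into events, attach
# behavioral contexts, map behaviors to categories, count per night hour.

# Ethogram: behavior name -> category. Four categories: aggression-,
# social-, sleep-related, and other behaviors.
.behaviorDict <- c(
  "Agonistic support"        = "aggression",
  "Ground slap"              = "aggression",
  "Long lunge"               = "aggression",
  "Short lunge"              = "aggression",
  "Redirection"              = "aggression",
  "Stare"                    = "aggression",
  "Bridging"                 = "social",
  "Embrace"                  = "social",
  "Holding an infant"        = "social",
  "Homosexual mount"         = "social",
  "Proximity < 1 m"          = "social",
  "Penis showing"            = "social",
  "Penis sucking"            = "social",
  "Huddling sleep"           = "sleep",
  "Sleep"                    = "sleep",
  "Sleeping with eyes closed" = "sleep",
  "Wake up with eyes open"   = "sleep",
  "Raise the head"           = "sleep",
  "Appear"                   = "other",
  "Self-scratch"             = "other",
  "Sit"                      = "other"
)

#' The shipped ethogram: behavior names and their categories
#'
#' @return named character vector mapping each behavior name to one of
#'   `"aggression"`, `"social"`, `"sleep"`, `"other"`.
#' @export
#' @examples
#' behaviorCategories()[c("Bridging", "Stare")]
behaviorCategories <- function() .behaviorDict

#' Map behavior names to their category
#'
#' @param behavior character vector of behavior names; every name must be
#'   present in [behaviorCategories()] — unknown names raise an error
#'   rather than being silently binned as "other".
#' @return character vector of categories.
#' @export
#' @examples
#' classifyBehavior(c("Bridging", "Stare", "Huddling sleep"))
classifyBehavior <- function(behavior) {
  out <- unname(.behaviorDict[as.character(behavior)])
  if (anyNA(out)) {
    bad <- unique(as.character(behavior)[is.na(out)])
    stop("unmapped behavior: ", paste(bad, collapse = ", "))
  }
  out
}

#' Merge raw calls into vocal events
#'
#' Calls separated by less than `gapS` seconds (strictly less; a gap of
#' exactly `gapS` starts a new event) are merged into a single vocal
#' event. By default calls are merged globally, appropriate when callers
#' are mostly unidentified at night; with `perCaller = TRUE` the rule is
#' applied within each caller's call stream.
#'
#' @param times call timestamps (`POSIXct` or numeric seconds); duplicates
#'   allowed, order arbitrary.
#' @param callerId optional caller identities, same length as `times`.
#' @param gapS merge threshold in seconds (default 5).
#' @param perCaller merge within caller streams instead of globally.
#' @return data.frame with `event_id`, `start`, `end`, `n_calls`,
#'   `caller_id` (the common caller, or `NA` if mixed/unknown), sorted by
#'   `start`. Sum of `n_calls` equals `length(times)`.
#' @export
#' @examples
#' mergeCalls(c(0, 3, 9))       # gaps 3, 6 -> two events
#' mergeCalls(c(0, 5))          # gap exactly 5 -> not merged
mergeCalls <- function(times, callerId = NULL, gapS = 5,
                       perCaller = FALSE) {
  n <- length(times)
  empty <- data.frame(event_id = integer(), start = times[0],
                      end = times[0], n_calls = integer(),
                      caller_id = character())
  if (n == 0) return(empty)
  if (perCaller && is.null(callerId))
    stop("perCaller merging needs callerId")
  if (!is.null(callerId)) stopifnot(length(callerId) == n)

  mergeOne <- function(t, ids) {
    o <- order(t)
    t <- t[o]
    ids <- if (is.null(ids)) rep(NA_character_, length(t))
           else as.character(ids)[o]
    grp <- cumsum(c(TRUE, diff(as.numeric(t)) >= gapS))
    idx <- split(seq_along(t), grp)
    data.frame(
      start = t[vapply(idx, min, 1L)],
      end = t[vapply(idx, max, 1L)],
      n_calls = lengths(idx),
      caller_id = vapply(idx, function(i) {
        u <- unique(ids[i])
        if (length(u) == 1) u else NA_character_
      }, character(1)),
      row.names = NULL
    )
  }

  out <- if (perCaller) {
    key <- ifelse(is.na(callerId), "<unknown>", as.character(callerId))
    parts <- lapply(split(seq_len(n), key), function(i)
      mergeOne(times[i], callerId[i]))
    do.call(rbind, parts)
  } else {
    mergeOne(times, callerId)
  }
  out <- out[order(out$start), , drop = FALSE]
  out <- cbind(event_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Attach pre/post behavioral contexts to vocal events
#'
#' Collects behavior records within `windowS` seconds before each event's
#' first call (`pre`), within `windowS` seconds after its last call
#' (`post`), and during the event itself (`during`). Both context
#' boundaries are closed: a record exactly `windowS` seconds away is
#' included. A record may appear in the contexts of several events.
#' Records falling strictly inside the event are returned in the `during`
#' phase, which downstream summaries exclude.
#'
#' @param events data.frame from [mergeCalls()] (columns `event_id`,
#'   `start`, `end`).
#' @param log behavior log data.frame with columns `time`,
#'   `individual_id`, `behavior` (names from [behaviorCategories()]).
#' @param windowS context half-window in seconds (default 10).
#' @return long data.frame: `event_id`, `event_start`, `phase`
#'   (`pre`/`during`/`post`), `time`, `individual_id`, `behavior`,
#'   `category`.
#' @export
attachContext <- function(events, log, windowS = 10) {
  cols <- data.frame(event_id = integer(), event_start = events$start[0],
                     phase = character(), time = log$time[0],
                     individual_id = character(), behavior = character(),
                     category = character())
  if (nrow(events) == 0 || nrow(log) == 0) return(cols)
  cat <- classifyBehavior(log$behavior)
  tt <- as.numeric(log$time)
  pieces <- lapply(seq_len(nrow(events)), function(i) {
    s <- as.numeric(events$start[i]); e <- as.numeric(events$end[i])
    phase <- rep(NA_character_, length(tt))
    phase[tt >= s - windowS & tt <= s] <- "pre"
    phase[tt > s & tt < e] <- "during"
    phase[tt >= e & tt <= e + windowS] <- "post"
    # a record at the instant of a single-call event (s == e) is "post"
    keep <- which(!is.na(phase))
    if (!length(keep)) return(NULL)
    data.frame(event_id = events$event_id[i],
               event_start = events$start[i],
               phase = phase[keep],
               time = log$time[keep],
               individual_id = as.character(log$individual_id[keep]),
               behavior = as.character(log$behavior[keep]),
               category = cat[keep],
               row.names = NULL)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) cols else out
}

#' Count vocal events per clock hour of the night window
#'
#' Events are binned by the clock hour of their start time. Hours are
#' ordered from `nightStart`, wrapping midnight; every hour of the window
#' appears, including empty ones. Events outside the window are dropped;
#' their number is reported via a message and the `"n_excluded"`
#' attribute.
#'
#' @param events data.frame with a `start` column (`POSIXct` or numeric
#'   seconds).
#' @param nightStart,nightEnd night window clock hours (default
#'   17:00-06:00, end exclusive).
#' @return data.frame with `hour` (night order) and `n_events`; attribute
#'   `n_excluded`.
#' @export
hourlyCounts <- function(events, nightStart = 17, nightEnd = 6) {
  hours <- nightHourSeq(nightStart, nightEnd)
  h <- hourOf(events$start)
  inWin <- !is.na(nightIndex(h, nightStart, nightEnd))
  nExcl <- sum(!inWin)
  if (nExcl > 0)
    message(nExcl, " event(s) outside the ", nightStart, ":00-",
            nightEnd, ":00 night window were excluded")
  tab <- table(factor(h[inWin], levels = hours))
  out <- data.frame(hour = hours, n_events = as.integer(tab))
  attr(out, "n_excluded") <- nExcl
  out
}

#' Hour x category table of context behaviors
#'
#' Counts behavior records in the pre/post contexts of vocal events by
#' the clock hour of the event start and the behavior category. Records
#' shared by several events are counted once per context (per-context
#' counting); `during`-phase records are excluded.
#'
#' @param contexts data.frame from [attachContext()].
#' @param nightStart,nightEnd night window (rows cover all its hours).
#' @return integer matrix, rows = night hours, columns = the four
#'   behavior categories.
#' @export
contextCategoryTable <- function(contexts, nightStart = 17, nightEnd = 6) {
  hours <- nightHourSeq(nightStart, nightEnd)
  cats <- c("aggression", "social", "sleep", "other")
  if (nrow(contexts) == 0) {
    m <- matrix(0L, length(hours), length(cats),
                dimnames = list(hours, cats))
    return(m)
  }
  keep <- contexts$phase %in% c("pre", "post")
  h <- hourOf(contexts$event_start[keep])
  tab <- table(factor(h, levels = hours),
               factor(contexts$category[keep], levels = cats))
  m <- matrix(as.integer(tab), nrow = length(hours),
              dimnames = list(hours, cats))
  m
}
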