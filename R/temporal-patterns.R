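# Temporal-pattern stage: quartile-based peak/trough labelling, ACI-vs-
# count validation, smooth hour-of-night effect.

#' Quartile-based peak/normal/trough labels
#'
#' Descriptive labelling of an hourly activity series: values strictly
#' above the upper quartile (Q3) are `peak`, strictly below the lower
#' quartile (Q1) are `trough`, everything else (including ties with the
#' quartiles) is `normal`. Quartiles use linear interpolation between
#' order statistics ([stats::quantile()] type 7). Because quartiles are
#' rank statistics, the labels are invariant under any strictly monotone
#' increasing transform of the series. This rule describes the shape of
#' the series; it is not a test of bimodality.
#'
#' @param values numeric series, at least 4 values.
#' @return character vector of labels (`peak`/`normal`/`trough`).
#' @export
#' @examples
#' quartileClassify(c(1, 1, 1, 9))
quartileClassify <- function(values) {
  if (length(values) < 4) stop("series too short: need at least 4 values")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  ifelse(values > q[2], "peak", ifelse(values < q[1], "trough", "normal"))
}

#' Validate ACI against manual vocalization counts
#'
#' Rank correlation between matched hourly vocalization counts and hourly
#' ACI. Shapiro-Wilk normality tests of both series are reported (the
#' usual gate for choosing a rank correlation); the Spearman coefficient
#' and its p-value are always returned, with the gate outcome recorded.
#'
#' @param counts hourly vocalization counts.
#' @param aci hourly ACI values for the same hours, same length.
#' @return list with `rho`, `p`, `shapiro_p` (length-2: counts, aci), and
#'   `normal` (`TRUE` when both Shapiro-Wilk p > 0.05, `NA` if a test was
#'   not computable).
#' @export
validateAci <- function(counts, aci) {
  if (length(counts) != length(aci))
    stop("counts and aci must have the same length")
  if (length(counts) < 4) stop("need at least 4 matched hours")
  swp <- vapply(list(counts, aci), function(v) {
    tryCatch(shapiro.test(v)$p.value, error = function(e) NA_real_)
  }, numeric(1))
  ct <- suppressWarnings(cor.test(counts, aci, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value,
       shapiro_p = setNames(swp, c("counts", "aci")),
       normal = if (anyNA(swp)) NA else all(swp > 0.05))
}

#' Smooth test of the hour-of-night effect on counts
#'
#' Fits a Poisson generalized additive model
#' `count ~ s(hour index, k)` on per-night hourly counts, with the hour
#' axis wrapped so the night runs 0..12 from the evening start (a
#' thin-plate smooth on the wrapped axis; basis dimension 8 by default).
#' Tests whether the hourly rate varies non-linearly across the night.
#'
#' @param data data.frame with columns `night`, `hour` (clock hour), and
#'   `count`.
#' @param k basis dimension of the smooth (default 8).
#' @param nightStart clock hour where the wrapped axis starts (default
#'   17).
#' @return list with `edf`, `statistic` (chi-square), `p`, and the fitted
#'   `model`.
#' @export
hourSmoothTest <- function(data, k = 8, nightStart = 17) {
  stopifnot(all(c("night", "hour", "count") %in% names(data)))
  if (length(unique(data$night)) < 2 || length(unique(data$hour)) < 6)
    stop("insufficient data: need >= 2 nights and >= 6 distinct hours")
  df <- data.frame(count = data$count,
                   hidx = (data$hour - nightStart) %% 24)
  kUse <- min(k, length(unique(df$hidx)) - 1)
  fit <- mgcv::gam(count ~ s(hidx, k = kUse), family = stats::poisson(),
                   data = df, method = "REML")
  st <- summary(fit)$s.table
  list(edf = unname(st[1, "edf"]),
       statistic = unname(st[1, "Chi.sq"]),
       p = unname(st[1, "p-value"]),
       model = fit)
}
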