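# Inferential stage: VIF screen, Poisson GLMM of individual counts,
# candidate GAMs of ACI on weather with backward smooth removal, Friedman
# test of behavioral rhythms.

#' Variance inflation factors of a predictor table
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the linear
#' regression of predictor `j` on all the others. Factors are expanded to
#' indicator columns via [stats::model.matrix()]. Values below 5 are the
#' usual all-clear for multicollinearity.
#'
#' @param design data.frame or matrix of predictors (no response).
#' @return named numeric vector of VIFs; perfectly collinear predictors
#'   get `Inf` with a warning naming the culprit.
#' @export
#' @examples
#' vif(data.frame(a = rnorm(50), b = rnorm(50)))
vif <- function(design) {
  mm <- model.matrix(~ ., data = as.data.frame(design))[, -1, drop = FALSE]
  p <- ncol(mm)
  if (p < 2) stop("need at least 2 predictors")
  if (nrow(mm) <= p) stop("need more observations than predictors")
  out <- vapply(seq_len(p), function(j) {
    y <- mm[, j]
    x <- mm[, -j, drop = FALSE]
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(NA_real_)
    fit <- stats::lm.fit(cbind(1, x), y)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(mm)
  if (any(is.infinite(out)))
    warning("perfect collinearity involving: ",
            paste(names(out)[is.infinite(out)], collapse = ", "))
  out
}

#' Poisson mixed model of individual vocalization counts
#'
#' Fits `count ~ rank + sex + age + centrality + relatives + (1 | id)`
#' with a Poisson log link via [lme4::glmer()]. Sex is coded with male as
#' the reference level (the female indicator enters the design), and the
#' continuous predictors (rank score, age, centrality, relatives) are
#' z-scored by default. With a single observation per individual the
#' random intercept is not estimable and the model degrades to a
#' fixed-effects GLM with a warning.
#'
#' @param data data.frame with columns `id`, `sex` (`"male"`/`"female"`),
#'   `age`, `centrality`, `relatives`, `rank`, `count`, optionally an
#'   exposure column.
#' @param rankAs `"score"` (continuous David's Score, default) or
#'   `"tier"` (3-level factor, which must then be in `rank`).
#' @param standardize z-score the continuous predictors (default `TRUE`;
#'   set `FALSE` when the inputs are already on the model scale, as the
#'   synthetic generator's are).
#' @param offsetLog optional name of a column whose log is used as an
#'   exposure offset (e.g. hours recorded).
#' @return data.frame (one row per fixed effect): `term`, `estimate`,
#'   `se`, `z`, `p`, `ci_lo`, `ci_hi` (Wald 95%). Attributes: `model`
#'   (the fit), `vif` (collinearity screen of the fixed-effect design),
#'   `random` (`TRUE` if the random intercept was kept).
#' @export
fitCountGlmm <- function(data, rankAs = c("score", "tier"),
                         standardize = TRUE, offsetLog = NULL) {
  rankAs <- match.arg(rankAs)
  need <- c("id", "sex", "age", "centrality", "relatives", "rank", "count")
  stopifnot(all(need %in% names(data)))
  if (any(data$count < 0) || any(data$count != round(data$count)))
    stop("non-integer counts: the response must be nonnegative integers")
  df <- data.frame(
    id = factor(data$id),
    sex = factor(data$sex, levels = c("male", "female")),
    age = data$age, centrality = data$centrality,
    relatives = data$relatives, count = data$count
  )
  df$rank <- if (rankAs == "tier") factor(data$rank) else data$rank
  if (standardize) {
    for (v in c("age", "centrality", "relatives",
                if (rankAs == "score") "rank"))
      df[[v]] <- as.numeric(scale(df[[v]]))
  }
  vifs <- vif(df[, c("rank", "sex", "age", "centrality", "relatives")])

  form <- count ~ rank + sex + age + centrality + relatives + (1 | id)
  if (!is.null(offsetLog)) {
    df$.expo <- data[[offsetLog]]
    form <- stats::update(form, . ~ . + offset(log(.expo)))
  }
  hasReplicates <- max(table(df$id)) >= 2
  if (hasReplicates) {
    fit <- lme4::glmer(form, data = df, family = stats::poisson())
    conv <- fit@optinfo$conv$opt
    if (!is.null(conv) && conv != 0)
      stop("GLMM did not converge (optimizer code ", conv, "): ",
           paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
    cf <- summary(fit)$coefficients
  } else {
    warning("single observation per individual; the random intercept is ",
            "not estimable - fitting a fixed-effects GLM instead")
    form <- stats::as.formula(
      paste("count ~ rank + sex + age + centrality + relatives",
            if (!is.null(offsetLog)) "+ offset(log(.expo))" else ""))
    fit <- stats::glm(form, data = df, family = stats::poisson())
    cf <- summary(fit)$coefficients
  }
  out <- data.frame(term = rownames(cf),
                    estimate = cf[, 1], se = cf[, 2],
                    z = cf[, 3], p = cf[, 4],
                    ci_lo = cf[, 1] - 1.96 * cf[, 2],
                    ci_hi = cf[, 1] + 1.96 * cf[, 2],
                    row.names = NULL)
  attr(out, "model") <- fit
  attr(out, "vif") <- vifs
  attr(out, "random") <- hasReplicates
  out
}

# Weather covariates entering the ACI GAM, in fixed term order (the order
# also breaks ties during backward removal).
.gamCovariates <- c("temperature", "humidity", "precipitation",
                    "zonal_wind", "meridional_wind", "surface_wind_speed",
                    "wind_direction", "surface_radiation")

.gamTermLabel <- function(covs, kMain, kTensor) {
  vapply(covs, function(v) {
    if (v == "wind_direction")
      sprintf("s(wind_direction, bs = 'cc', k = %d)", kMain[[v]])
    else if (grepl(":", v, fixed = TRUE)) {
      parts <- strsplit(v, ":", fixed = TRUE)[[1]]
      sprintf("ti(%s, %s, k = %d)", parts[1], parts[2], kTensor)
    } else sprintf("s(%s, k = %d)", v, kMain[[v]])
  }, character(1))
}

#' GAM of ACI on weather with candidate selection and backward removal
#'
#' Fits four candidate generalized additive models of hourly ACI on the
#' weather covariates — main effects only, plus a temperature x humidity
#' tensor interaction, plus a temperature x precipitation interaction, or
#' both — using [mgcv::gam()] with thin-plate smooths (cyclic basis for
#' wind direction, tensor-product `ti()` smooths for the interactions).
#' The candidate with the lowest AIC is then pruned by backward removal:
#' while any smooth has `p >= alpha`, the one with the largest p-value is
#' dropped (ties broken by term order) and the model refitted, possibly
#' down to an intercept-only model.
#'
#' @param aci data.frame with an `aci` column and the weather columns, or
#'   just the ACI values if `weather` is supplied separately.
#' @param weather optional data.frame of weather covariates
#'   (`temperature`, `humidity`, `precipitation`, `zonal_wind`,
#'   `meridional_wind`, `surface_wind_speed`, `wind_direction`,
#'   `surface_radiation`), row-matched to `aci`.
#' @param alpha retention threshold for smooth terms (default 0.05).
#' @param k basis dimension for univariate smooths (default 8; reduced
#'   automatically when a covariate has few unique values).
#' @param kTensor marginal basis dimension for tensor interactions
#'   (default 5).
#' @return data.frame of retained smooth terms: `term`, `edf`, `ref_df`,
#'   `F`, `p`. Attributes: `model`, `adj_r2`, `candidate_aic` (named
#'   vector), `removal_trace` (data.frame of dropped terms and their
#'   p-values), `formula`.
#' @export
fitAciGam <- function(aci, weather = NULL, alpha = 0.05, k = 8,
                      kTensor = 5) {
  df <- if (is.null(weather)) as.data.frame(aci)
        else cbind(data.frame(aci = as.numeric(aci)), as.data.frame(weather))
  stopifnot("aci" %in% names(df), all(.gamCovariates %in% names(df)))
  nSmooth <- length(.gamCovariates) + 2
  if (nrow(df) < 10 * nSmooth)
    stop("need at least ", 10 * nSmooth, " observations (10 per smooth)")

  kMain <- lapply(.gamCovariates, function(v)
    max(3L, min(k, length(unique(df[[v]])) - 1L)))
  names(kMain) <- .gamCovariates
  knots <- list(wind_direction = c(0, 360))

  fitOne <- function(covs) {
    if (length(covs) == 0)
      return(mgcv::gam(aci ~ 1, data = df, method = "REML"))
    rhs <- paste(.gamTermLabel(covs, kMain, kTensor), collapse = " + ")
    mgcv::gam(as.formula(paste("aci ~", rhs)), data = df,
              knots = knots, method = "REML")
  }

  candidates <- list(
    main            = .gamCovariates,
    temp_x_humidity = c(.gamCovariates, "temperature:humidity"),
    temp_x_precip   = c(.gamCovariates, "temperature:precipitation"),
    both            = c(.gamCovariates, "temperature:humidity",
                        "temperature:precipitation")
  )
  fits <- lapply(names(candidates), function(nm) {
    tryCatch(fitOne(candidates[[nm]]),
             error = function(e) {
               warning("candidate '", nm, "' failed to fit: ",
                       conditionMessage(e))
               NULL
             })
  })
  names(fits) <- names(candidates)
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all candidate GAMs failed to fit")
  aics <- vapply(fits[ok], AIC, numeric(1))
  best <- names(aics)[which.min(aics)]
  covs <- candidates[[best]]
  fit <- fits[[best]]

  trace <- data.frame(term = character(), p = numeric())
  repeat {
    if (length(covs) == 0) break
    st <- summary(fit)$s.table
    pvals <- st[, "p-value"]
    if (all(pvals < alpha)) break
    dropIdx <- which.max(pvals)  # ties: first in term order
    trace <- rbind(trace, data.frame(term = rownames(st)[dropIdx],
                                     p = unname(pvals[dropIdx])))
    covs <- covs[-dropIdx]
    fit <- fitOne(covs)
  }

  if (length(covs) > 0) {
    st <- summary(fit)$s.table
    out <- data.frame(term = rownames(st),
                      edf = st[, "edf"], ref_df = st[, "Ref.df"],
                      F = st[, "F"], p = st[, "p-value"],
                      row.names = NULL)
  } else {
    out <- data.frame(term = character(), edf = numeric(),
                      ref_df = numeric(), F = numeric(), p = numeric())
  }
  attr(out, "model") <- fit
  attr(out, "adj_r2") <- summary(fit)$r.sq
  attr(out, "candidate_aic") <- aics
  attr(out, "removal_trace") <- trace
  attr(out, "formula") <- stats::formula(fit)
  out
}

#' Friedman test of behavioral rhythms across the night
#'
#' Compares behavior-category frequencies across night hours with the
#' Friedman rank test: hours are the blocks, categories the treatments,
#' ranked within each hour (average ranks for ties). Sleep-related
#' behaviors are excluded by default so the comparison covers the
#' aggression / social / other categories; include them with
#' `includeSleep = TRUE`. A table with no within-hour variation returns
#' statistic 0 and p = 1.
#'
#' @param tab numeric matrix, rows = hours (blocks), columns = behavior
#'   categories (treatments), as from [contextCategoryTable()].
#' @param includeSleep keep a `sleep` column if present (default
#'   `FALSE`).
#' @return list with `statistic` (chi-square), `df`, and `p`.
#' @export
friedmanBehaviorTest <- function(tab, includeSleep = FALSE) {
  tab <- as.matrix(tab)
  if (!includeSleep && "sleep" %in% colnames(tab))
    tab <- tab[, colnames(tab) != "sleep", drop = FALSE]
  if (ncol(tab) < 3) stop("need at least 3 behavior categories")
  if (nrow(tab) < 2) stop("need at least 2 hours (blocks)")
  if (all(apply(tab, 1, function(r) diff(range(r)) == 0)))
    return(list(statistic = 0, df = ncol(tab) - 1, p = 1))
  ft <- friedman.test(tab)
  list(statistic = unname(ft$statistic),
       df = unname(ft$parameter),
       p = ft$p.value)
}
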