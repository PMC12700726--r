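# Synthetic-data generators: night soundscapes with planted calls,
# call/behavior logs, social observation records, individual attributes
# with Poisson-mixed-model counts, and autocorrelated weather series.
# Every generator draws from its own derived seed and restores the
# caller's RNG state, so a fixed config seed gives identical output.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators with defaults
#' matching the monitored study system: a 17:00-06:00 night window, a
#' bimodal hourly call-rate profile peaking at 18:00-19:00 and
#' 21:00-23:00 with a trough at 02:00-04:00, 24 focal individuals,
#' 48 kHz audio, and count-model coefficients at field-realistic values
#' (intercept 7.748, rank -0.285, sex(female) -1.909, age -1.342,
#' centrality -2.163, relatives 0.249 on z-scored predictors).
#'
#' @param seed master RNG seed; all generators derive their streams from
#'   it (same seed, same outputs).
#' @param nIndividuals number of monitored individuals.
#' @param nNights number of recording nights.
#' @param sampleRate audio sampling rate in Hz.
#' @param dutySeconds seconds of audio rendered per hour: each hour's
#'   soundscape is written onto a short duty-cycle segment that carries
#'   the hour's full call count, preserving the hourly rate structure at
#'   desk scale.
#' @param nightStart,nightEnd night window clock hours (end exclusive).
#' @param hourlyRates named vector of expected calls per hour over the
#'   night window (names = clock hours). `NULL` for the default bimodal
#'   profile.
#' @param callTemplate list describing the synthetic call: fundamental
#'   `f0` (Hz), `nHarmonics`, `duration` (s), `amplitude` (linear, of
#'   full scale), `fmSweep` (fractional upward frequency sweep over the
#'   call), `vibratoHz` and `vibratoDepth` (frequency modulation). The
#'   modulation matters: it moves energy across frequency bins so calls
#'   raise the ACI above the noise floor.
#' @param noiseFloor standard deviation of the background noise at zero
#'   wind.
#' @param windNoiseCoef added noise s.d. per m/s of surface wind speed.
#' @param betas named fixed-effect coefficients of the count generator
#'   (log scale, z-scored predictors).
#' @param sigmaId standard deviation of the per-individual random
#'   intercept.
#' @param hierarchy list with `steepness` (logistic slope of win
#'   probability on rank distance) and `meanInteractions` (mean agonistic
#'   bouts per dyad).
#' @param kinClusterSize matriline size used for pedigree and proximity
#'   structure.
#' @param focalSeconds focal observation time per individual (s).
#' @param behaviorMeanPerCall mean number of context behavior records
#'   generated around each call.
#' @param weather list of weather-process parameters: AR(1) coefficient
#'   `phi`, marginal means/s.d. of temperature (deg C), humidity (%),
#'   wind components (m/s), precipitation latent scale (mm), radiation
#'   scale (W/m2).
#' @return object of class `SimulationConfig` (a validated list).
#' @export
#' @examples
#' cfg <- simConfig(seed = 42, nIndividuals = 10)
#' cfg$hourlyRates
simConfig <- function(seed = 1L,
                      nIndividuals = 24L,
                      nNights = 30L,
                      sampleRate = 48000,
                      dutySeconds = 60,
                      nightStart = 17, nightEnd = 6,
                      hourlyRates = NULL,
                      callTemplate = list(f0 = 520, nHarmonics = 5,
                                          duration = 0.35, amplitude = 0.5,
                                          fmSweep = 0.4, vibratoHz = 6,
                                          vibratoDepth = 0.03),
                      noiseFloor = 0.005,
                      windNoiseCoef = 0.003,
                      betas = c(intercept = 7.748, rank = -0.285,
                                sexfemale = -1.909, age = -1.342,
                                centrality = -2.163, relatives = 0.249),
                      sigmaId = 0.5,
                      hierarchy = list(steepness = 0.75,
                                       meanInteractions = 8),
                      kinClusterSize = 4L,
                      focalSeconds = 3600,
                      behaviorMeanPerCall = 1.5,
                      weather = list(phi = 0.8, tempMean = 5, tempSd = 3,
                                     humMean = 75, humSd = 10,
                                     windSd = 1.8, precipMean = -1,
                                     precipSd = 1.2, radSd = 1.5)) {
  hours <- nightHourSeq(nightStart, nightEnd)
  if (is.null(hourlyRates)) {
    hourlyRates <- setNames(
      c(6, 18, 16, 6, 14, 16, 13, 5, 4, 2, 2, 2, 4)[seq_along(hours)],
      hours)
  }
  stopifnot(length(hourlyRates) == length(hours), all(hourlyRates >= 0),
            nIndividuals >= 1, nNights >= 1, sampleRate > 0,
            dutySeconds > 0, all(is.finite(betas)), sigmaId >= 0)
  if (is.null(names(hourlyRates))) names(hourlyRates) <- hours
  structure(list(
    seed = as.integer(seed), nIndividuals = as.integer(nIndividuals),
    nNights = as.integer(nNights), sampleRate = sampleRate,
    dutySeconds = dutySeconds, nightStart = nightStart,
    nightEnd = nightEnd, hourlyRates = hourlyRates,
    callTemplate = callTemplate, noiseFloor = noiseFloor,
    windNoiseCoef = windNoiseCoef, betas = betas, sigmaId = sigmaId,
    hierarchy = hierarchy, kinClusterSize = as.integer(kinClusterSize),
    focalSeconds = focalSeconds,
    behaviorMeanPerCall = behaviorMeanPerCall, weather = weather
  ), class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig: seed", x$seed, "|", x$nIndividuals,
      "individuals,", x$nNights, "nights |",
      sprintf("%g Hz, %g s/hour audio\n", x$sampleRate, x$dutySeconds))
  cat("  night window:", x$nightStart, ":00 -", x$nightEnd, ":00\n")
  cat("  hourly call rates:",
      paste(names(x$hourlyRates), x$hourlyRates, sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

.simIds <- function(cfg) sprintf("id%02d", seq_len(cfg$nIndividuals))

# Frequency-modulated harmonic-stack call (tremolo + upward sweep).
.synthCall <- function(template, sampleRate) {
  n <- max(2L, round(template$duration * sampleRate))
  t <- seq_len(n) / sampleRate
  f <- template$f0 * (1 + template$fmSweep * t / template$duration +
                        template$vibratoDepth *
                          sin(2 * pi * template$vibratoHz * t))
  phase <- 2 * pi * cumsum(f) / sampleRate
  env <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))  # Hann envelope
  h <- seq_len(template$nHarmonics)
  wave <- rowSums(vapply(h, function(k) sin(k * phase) / k, numeric(n)))
  wave <- wave / max(abs(wave))
  template$amplitude * env * wave
}

#' Generate one night of soundscape audio with planted calls
#'
#' Call times follow an inhomogeneous Poisson process with the
#' configured hourly rate profile. Each hour's calls are synthesized as
#' frequency-modulated harmonic stacks and placed on a `dutySeconds`-long
#' audio segment for that hour, on top of Gaussian noise whose level
#' grows with the hour's surface wind speed. The full call log (times
#' spread over the real hour) and the ground truth are returned alongside
#' the audio.
#'
#' @param cfg a [simConfig()].
#' @param night night index (shifts the date and the derived seed).
#' @param sampleRate,dutySeconds override the config values (e.g. a lower
#'   rate for fast tests).
#' @param windSpeed optional vector of surface wind speed (m/s) per night
#'   hour, recycling a scalar; default 2 m/s.
#' @param outDir if non-`NULL`, one 16-bit WAV per hour is written there.
#' @param seed RNG seed; defaults to `cfg$seed + night`.
#' @return list with `segments` (named list of waveforms, names = clock
#'   hour), `sampleRate`, `dutySeconds`, `date` (midnight anchoring the
#'   night), `calls` (data.frame `time`, `hour`, `caller_id`), and
#'   `truth` (hourly rates, planted call counts, wind speeds, call
#'   positions on each segment).
#' @export
genNightAudio <- function(cfg, night = 1,
                          sampleRate = cfg$sampleRate,
                          dutySeconds = cfg$dutySeconds,
                          windSpeed = 2,
                          outDir = NULL,
                          seed = cfg$seed + night) {
  hours <- nightHourSeq(cfg$nightStart, cfg$nightEnd)
  windSpeed <- rep_len(windSpeed, length(hours))
  date <- simEpoch() + (night - 1) * 86400
  ids <- .simIds(cfg)
  template <- cfg$callTemplate
  withSeed(seed, {
    call1 <- .synthCall(template, sampleRate)
    nSamp <- round(dutySeconds * sampleRate)
    segments <- vector("list", length(hours))
    names(segments) <- hours
    callRows <- list()
    nCalls <- integer(length(hours))
    positions <- vector("list", length(hours))
    for (j in seq_along(hours)) {
      h <- hours[j]
      lam <- unname(cfg$hourlyRates[as.character(h)])
      nc <- rpois(1, lam)
      nCalls[j] <- nc
      sdNoise <- cfg$noiseFloor + cfg$windNoiseCoef * windSpeed[j]
      seg <- rnorm(nSamp, 0, sdNoise)
      pos <- numeric(0)
      if (nc > 0) {
        pos <- sort(runif(nc, 0, max(0, dutySeconds - template$duration)))
        for (p in pos) {
          i0 <- round(p * sampleRate)
          idx <- i0 + seq_along(call1)
          idx <- idx[idx <= nSamp]
          seg[idx] <- seg[idx] + call1[seq_along(idx)]
        }
        dayOff <- if (h < cfg$nightStart) 1 else 0
        tms <- date + dayOff * 86400 + h * 3600 + sort(runif(nc, 0, 3600))
        callRows[[j]] <- data.frame(
          time = tms, hour = h,
          caller_id = ifelse(runif(nc) < 0.5, sample(ids, nc, TRUE),
                             NA_character_))
      }
      positions[[j]] <- pos
      segments[[j]] <- seg
    }
    calls <- if (length(callRows)) do.call(rbind, callRows)
             else data.frame(time = simEpoch()[0], hour = integer(),
                             caller_id = character())
    rownames(calls) <- NULL
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      for (j in seq_along(hours))
        writeWav(segments[[j]], sampleRate,
                 file.path(outDir, sprintf("night%02d_hour%02d.wav",
                                           night, hours[j])))
    }
    list(segments = segments, sampleRate = sampleRate,
         dutySeconds = dutySeconds, date = date, calls = calls,
         truth = list(hourlyRates = cfg$hourlyRates, nCalls = nCalls,
                      windSpeed = windSpeed, positions = positions))
  })
}

# Hour-dependent category mixing weights: aggression-heavy around 18:00,
# social-heavy around 21:00-22:00, sleep rising late, other flat.
.behaviorWeights <- function(hours, nightStart = 17) {
  hs <- (hours - nightStart) %% 24
  w <- cbind(
    aggression = 0.20 + 1.20 * exp(-((hs - 1) / 1.5)^2),
    social     = 0.20 + 1.40 * exp(-((hs - 4.5) / 1.5)^2),
    sleep      = 0.10 + 0.60 * plogis((hs - 6) / 2),
    other      = 0.40
  )
  sweep(w, 1, rowSums(w), "/")
}

#' Generate a behavior log around planted calls
#'
#' For each call, a Poisson number of behavior records is placed within
#' 10 s of the call time; the category mix depends on the clock hour
#' (aggression-heavy near 18:00, social-heavy near 21:00-22:00, with
#' sleep-related behaviors increasing late in the night), and a behavior
#' name is drawn uniformly within the category.
#'
#' @param cfg a [simConfig()].
#' @param calls call log data.frame (columns `time`, `hour`) as from
#'   [genNightAudio()].
#' @param seed RNG seed; default derives from the config.
#' @return data.frame `time`, `individual_id`, `behavior` plus a `truth`
#'   attribute holding the hour x category weight matrix.
#' @export
genBehaviors <- function(cfg, calls, seed = cfg$seed + 77) {
  hours <- nightHourSeq(cfg$nightStart, cfg$nightEnd)
  W <- .behaviorWeights(hours, cfg$nightStart)
  rownames(W) <- hours
  dict <- behaviorCategories()
  ids <- .simIds(cfg)
  withSeed(seed, {
    rows <- lapply(seq_len(nrow(calls)), function(i) {
      nb <- rpois(1, cfg$behaviorMeanPerCall)
      if (nb == 0) return(NULL)
      h <- as.character(calls$hour[i])
      catDraw <- sample(colnames(W), nb, TRUE, prob = W[h, ])
      beh <- vapply(catDraw, function(cc)
        sample(names(dict)[dict == cc], 1), character(1))
      data.frame(time = calls$time[i] + runif(nb, -10, 10),
                 individual_id = sample(ids, nb, TRUE),
                 behavior = beh, row.names = NULL)
    })
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(time = simEpoch()[0],
                           individual_id = character(),
                           behavior = character())
    rownames(out) <- NULL
    attr(out, "truth") <- W
    out
  })
}

#' Generate social observation records with planted structure
#'
#' Produces proximity, agonistic, and pedigree records for a group with
#' a planted linear dominance hierarchy (the probability that the
#' higher-ranked member of a dyad wins a bout follows a logistic curve in
#' rank distance) and matriline kin clusters (proximity time concentrated
#' within clusters; pedigree links one mother to the rest of her
#' cluster).
#'
#' @param cfg a [simConfig()] (`nIndividuals >= 3`).
#' @param seed RNG seed; default derives from the config.
#' @return list with `ids`, `proximity` (list: `dyadSeconds` matrix,
#'   `focalSeconds` vector), `agonistic` (win-count matrix), `pedigree`
#'   (data.frame `parent`, `offspring`), and `truth` (hierarchy order =
#'   `ids` from top to bottom, kin `clusters`).
#' @export
genSocial <- function(cfg, seed = cfg$seed + 7) {
  n <- cfg$nIndividuals
  if (n < 3) stop("need at least 3 individuals")
  ids <- .simIds(cfg)
  clusters <- split(ids, ceiling(seq_along(ids) / cfg$kinClusterSize))
  withSeed(seed, {
    dy <- matrix(0, n, n, dimnames = list(ids, ids))
    member <- rep(seq_along(clusters), lengths(clusters))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      s <- if (member[i] == member[j]) runif(1, 600, 1200)
           else runif(1, 0, 120)
      dy[i, j] <- dy[j, i] <- round(s)
    }
    focal <- setNames(rep(cfg$focalSeconds, n), ids)

    W <- matrix(0L, n, n, dimnames = list(ids, ids))
    st <- cfg$hierarchy$steepness
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      nb <- rpois(1, cfg$hierarchy$meanInteractions)
      if (nb == 0) next
      pWin <- plogis(st * (j - i))  # i outranks j
      wij <- rbinom(1, nb, pWin)
      W[i, j] <- wij
      W[j, i] <- nb - wij
    }

    ped <- do.call(rbind, lapply(clusters, function(cl) {
      if (length(cl) < 2) return(NULL)
      data.frame(parent = cl[1], offspring = cl[-1])
    }))
    rownames(ped) <- NULL
    list(ids = ids,
         proximity = list(dyadSeconds = dy, focalSeconds = focal),
         agonistic = W, pedigree = ped,
         truth = list(order = ids, clusters = clusters))
  })
}

#' Generate individual attributes and counts from the Poisson mixed model
#'
#' Runs the count model forward: per individual, sex, age, centrality,
#' relatives, and rank score are drawn, z-scored, and combined with the
#' configured coefficients and a Normal random intercept; each night's
#' count is Poisson with that individual's rate. The returned table holds
#' the standardized predictors (the model scale), so it can be fed to
#' [fitCountGlmm()] with `standardize = FALSE` for exact recovery
#' checks.
#'
#' @param cfg a [simConfig()].
#' @param nIndividuals,nNights override the config sizes.
#' @param betas,sigmaId override the generating coefficients / random-
#'   intercept s.d. (e.g. zero betas for null simulations).
#' @param seed RNG seed; default derives from the config.
#' @return list with `data` (data.frame: `id`, `night`, `sex`, `age`,
#'   `centrality`, `relatives`, `rank`, `count`) and `truth` (`betas`,
#'   `sigmaId`, per-individual random effects `ranef`).
#' @export
genCountsAndAttributes <- function(cfg,
                                   nIndividuals = cfg$nIndividuals,
                                   nNights = cfg$nNights,
                                   betas = cfg$betas,
                                   sigmaId = cfg$sigmaId,
                                   seed = cfg$seed + 13) {
  stopifnot(all(is.finite(betas)))
  withSeed(seed, {
    ids <- sprintf("id%02d", seq_len(nIndividuals))
    sex <- sample(c("male", "female"), nIndividuals, TRUE)
    z <- function(v) if (sd(v) > 0) as.numeric(scale(v)) else v - mean(v)
    age <- z(runif(nIndividuals, 4, 25))
    centrality <- z(rbeta(nIndividuals, 2, 2))
    relatives <- z(rpois(nIndividuals, 2))
    rank <- z(rnorm(nIndividuals, 0, 1.5))
    b <- rnorm(nIndividuals, 0, sigmaId)
    eta <- betas[["intercept"]] +
      betas[["rank"]] * rank +
      betas[["sexfemale"]] * (sex == "female") +
      betas[["age"]] * age +
      betas[["centrality"]] * centrality +
      betas[["relatives"]] * relatives + b
    idx <- rep(seq_len(nIndividuals), each = nNights)
    data <- data.frame(
      id = ids[idx], night = rep(seq_len(nNights), nIndividuals),
      sex = sex[idx], age = age[idx], centrality = centrality[idx],
      relatives = relatives[idx], rank = rank[idx],
      count = rpois(length(idx), exp(eta[idx]))
    )
    list(data = data,
         truth = list(betas = betas, sigmaId = sigmaId,
                      ranef = setNames(b, ids)))
  })
}

#' Generate an autocorrelated hourly weather series
#'
#' AR(1) processes (coefficient `phi`, stationary marginal moments from
#' the config) for temperature, humidity (clipped to 0-100%), zonal and
#' meridional wind; surface wind speed is the modulus of the wind vector,
#' wind direction its meteorological bearing (degrees the wind blows
#' from, in `[0, 360)`); precipitation is a rectified AR(1) (dry hours at
#' 0), radiation a small rectified residual term.
#'
#' @param cfg a [simConfig()].
#' @param nHours number of hourly records (>= 1).
#' @param seed RNG seed; default derives from the config.
#' @return data.frame with `time`, `hour`, `temperature`, `humidity`,
#'   `precipitation`, `zonal_wind`, `meridional_wind`,
#'   `surface_wind_speed`, `wind_direction`, `surface_radiation`.
#' @export
genWeather <- function(cfg, nHours, seed = cfg$seed + 29) {
  stopifnot(nHours >= 1)
  wp <- cfg$weather
  ar1 <- function(n, phi, mean, sdMarg) {
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sdMarg)
    sdInn <- sdMarg * sqrt(1 - phi^2)
    for (i in seq_len(n - 1)) x[i + 1] <- phi * x[i] + rnorm(1, 0, sdInn)
    mean + x
  }
  withSeed(seed, {
    u <- ar1(nHours, wp$phi, 0, wp$windSd)
    v <- ar1(nHours, wp$phi, 0, wp$windSd)
    data.frame(
      time = simEpoch() + cfg$nightStart * 3600 +
        (seq_len(nHours) - 1) * 3600,
      hour = (cfg$nightStart + seq_len(nHours) - 1) %% 24,
      temperature = ar1(nHours, wp$phi, wp$tempMean, wp$tempSd),
      humidity = pmin(100, pmax(0, ar1(nHours, wp$phi, wp$humMean,
                                       wp$humSd))),
      precipitation = pmax(0, ar1(nHours, wp$phi, wp$precipMean,
                                  wp$precipSd)),
      zonal_wind = u,
      meridional_wind = v,
      surface_wind_speed = sqrt(u^2 + v^2),
      wind_direction = (atan2(-u, -v) * 180 / pi) %% 360,
      surface_radiation = pmax(0, ar1(nHours, wp$phi, 0.5, wp$radSd))
    )
  })
}

#' Default weather-to-ACI coupling functions
#'
#' The planted partial effects used by [genCoupledAci()]: a unimodal
#' response to meridional wind, a decline with surface wind speed, a
#' periodic wind-direction effect with maxima at easterly (90 deg) and
#' westerly (270 deg) winds, and a temperature x humidity interaction
#' that raises ACI under cold, humid conditions.
#'
#' @return named list of functions of the corresponding weather columns.
#' @export
defaultAciCoupling <- function() {
  list(
    meridional_wind = function(v) 2.0 * exp(-(v / 1.5)^2),
    surface_wind_speed = function(w) -0.35 * w,
    wind_direction = function(th) 0.8 * cos(2 * (th - 90) * pi / 180),
    temperature_humidity = function(t, h)
      1.2 * (-(t - 5) / 3) * ((h - 75) / 10) / 2
  )
}

#' Generate an ACI series coupled to weather
#'
#' Sums the planted partial effects over a weather series and adds
#' Gaussian noise; the coupling functions are returned as ground truth
#' for recovery tests of the weather GAM.
#'
#' @param weather data.frame from [genWeather()].
#' @param coupling named list of effect functions; names are weather
#'   columns, or `"temperature_humidity"` /
#'   `"temperature_precipitation"` for bivariate interactions. `NULL`
#'   entries are allowed; an empty list gives pure noise.
#' @param noiseSd residual standard deviation (default 0.3).
#' @param baseline intercept (default 10).
#' @param seed RNG seed.
#' @return list with `aci` (numeric vector) and `truth` (the coupling
#'   list).
#' @export
genCoupledAci <- function(weather, coupling = defaultAciCoupling(),
                          noiseSd = 0.3, baseline = 10, seed = 101) {
  eta <- rep(baseline, nrow(weather))
  for (nm in names(coupling)) {
    f <- coupling[[nm]]
    if (is.null(f)) next
    eta <- eta + if (nm == "temperature_humidity")
      f(weather$temperature, weather$humidity)
    else if (nm == "temperature_precipitation")
      f(weather$temperature, weather$precipitation)
    else f(weather[[nm]])
  }
  withSeed(seed, list(aci = eta + rnorm(nrow(weather), 0, noiseSd),
                      truth = coupling))
}

#' Write a full synthetic data set as CSV (and optionally WAV) files
#'
#' Convenience exporter: generates one night of audio (WAVs optional),
#' the call and behavior logs, social records, attribute/count table,
#' and a weather series, and writes them as plain-text CSV under
#' `dir`.
#'
#' @param cfg a [simConfig()].
#' @param dir output directory (created if needed).
#' @param writeAudio also write per-hour WAV files (default `FALSE`).
#' @return invisibly, the list of generated objects.
#' @export
writeSimulation <- function(cfg, dir, writeAudio = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  night <- genNightAudio(cfg, outDir = if (writeAudio) dir else NULL)
  beh <- genBehaviors(cfg, night$calls)
  soc <- genSocial(cfg)
  cnt <- genCountsAndAttributes(cfg)
  wx <- genWeather(cfg, nHours = length(cfg$hourlyRates) * cfg$nNights)
  wcsv <- function(x, f) write.csv(x, file.path(dir, f), row.names = FALSE)
  wcsv(night$calls, "calls.csv")
  wcsv(beh, "behaviors.csv")
  dySec <- soc$proximity$dyadSeconds
  prox <- data.frame(id_a = rownames(dySec)[row(dySec)[upper.tri(dySec)]],
                     id_b = colnames(dySec)[col(dySec)[upper.tri(dySec)]],
                     seconds = dySec[upper.tri(dySec)])
  wcsv(prox, "proximity.csv")
  wcsv(data.frame(id = names(soc$proximity$focalSeconds),
                  seconds = soc$proximity$focalSeconds), "focal.csv")
  W <- soc$agonistic
  ago <- data.frame(winner = rownames(W)[row(W)], loser = colnames(W)[col(W)],
                    count = as.vector(W))
  wcsv(ago[ago$count > 0, ], "agonistic.csv")
  wcsv(soc$pedigree, "pedigree.csv")
  wcsv(cnt$data, "attributes.csv")
  wcsv(wx, "weather.csv")
  invisible(list(night = night, behaviors = beh, social = soc,
                 counts = cnt, weather = wx))
}
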