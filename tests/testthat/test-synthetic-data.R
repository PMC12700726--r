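test_that("generators are deterministic under a fixed seed and leave the RNG alone", {
  cfg <- simConfig(seed = 99, sampleRate = 4000, dutySeconds = 5)
  set.seed(1234)
  before <- rnorm(3)
  set.seed(1234)
  a <- genNightAudio(cfg)
  b <- genNightAudio(cfg)
  expect_identical(a$segments, b$segments)
  expect_identical(a$calls, b$calls)
  after <- rnorm(3)
  expect_identical(before, after)  # caller RNG stream untouched

  expect_identical(genSocial(cfg), genSocial(cfg))
  expect_identical(genWeather(cfg, 50), genWeather(cfg, 50))
  expect_identical(genCountsAndAttributes(cfg),
                   genCountsAndAttributes(cfg))

  # different nights use different streams
  expect_false(identical(genNightAudio(cfg, night = 1)$segments,
                         genNightAudio(cfg, night = 2)$segments))
})

test_that("night audio plants the configured call process", {
  # silent profile: a valid silent night with an empty log
  cfg0 <- simConfig(seed = 7, sampleRate = 4000, dutySeconds = 5,
                    hourlyRates = setNames(rep(0, 13), nightHourSeq()),
                    noiseFloor = 0, windNoiseCoef = 0)
  night0 <- genNightAudio(cfg0)
  expect_equal(nrow(night0$calls), 0)
  expect_true(all(vapply(night0$segments, function(s) all(s == 0),
                         logical(1))))

  # zero noise, one planted call: energy only during the call
  cfg1 <- simConfig(seed = 7, sampleRate = 4000, dutySeconds = 10,
                    hourlyRates = setNames(c(5, rep(0, 12)),
                                           nightHourSeq()),
                    noiseFloor = 0, windNoiseCoef = 0)
  night1 <- genNightAudio(cfg1)
  seg <- night1$segments[["17"]]
  expect_gt(sum(seg^2), 0)
  expect_true(all(vapply(night1$segments[-1], function(s) all(s == 0),
                         logical(1))))
  # samples outside planted call positions are silent
  dur <- cfg1$callTemplate$duration
  pos <- night1$truth$positions[[1]]
  inCall <- rep(FALSE, length(seg))
  for (p in pos) {
    i0 <- round(p * 4000)
    inCall[i0 + seq_len(round(dur * 4000) + 2)] <- TRUE
  }
  expect_true(all(seg[!inCall[seq_along(seg)]] == 0))

  # doubling rates about doubles the planted call count (Poisson, 3 sigma)
  rates <- simConfig()$hourlyRates
  cfgA <- simConfig(seed = 15, sampleRate = 4000, dutySeconds = 5)
  cfgB <- simConfig(seed = 15, sampleRate = 4000, dutySeconds = 5,
                    hourlyRates = rates * 2)
  nA <- sum(vapply(1:8, function(k)
    nrow(genNightAudio(cfgA, night = k)$calls), numeric(1)))
  nB <- sum(vapply(1:8, function(k)
    nrow(genNightAudio(cfgB, night = k)$calls), numeric(1)))
  lamA <- sum(rates) * 8
  expect_lt(abs(nA - lamA), 3 * sqrt(lamA))
  expect_lt(abs(nB - 2 * lamA), 3 * sqrt(2 * lamA))
})

test_that("planted social structure is recoverable by the metrics", {
  # steep hierarchy: David's Scores recover the planted order
  recovered <- vapply(1:20, function(s) {
    cfg <- simConfig(seed = s, nIndividuals = 10,
                     hierarchy = list(steepness = 3,
                                      meanInteractions = 12))
    soc <- genSocial(cfg)
    ds <- davidsScore(soc$agonistic)
    all(order(ds, decreasing = TRUE) == seq_along(ds))
  }, logical(1))
  expect_gte(mean(recovered), 0.95)

  # kin clusters: within-cluster association exceeds between-cluster
  cfg <- simConfig(seed = 77, nIndividuals = 12)
  soc <- genSocial(cfg)
  M <- daiMatrix(soc$proximity$dyadSeconds, soc$proximity$focalSeconds)
  member <- rep(seq_along(soc$truth$clusters),
                lengths(soc$truth$clusters))
  same <- outer(member, member, "==") & upper.tri(M)
  diff <- outer(member, member, "!=") & upper.tri(M)
  expect_gt(mean(M[same]), mean(M[diff]))

  # pedigree of one mother and her offspring: known kinship counts
  counts <- kinshipCounts(soc$pedigree, soc$ids)
  firstCluster <- soc$truth$clusters[[1]]
  expect_equal(unname(counts[firstCluster]),
               rep(length(firstCluster) - 1L, length(firstCluster)))
})

test_that("the count generator reproduces its Poisson mixed model", {
  cfg <- simConfig(seed = 21)
  # all betas zero, no random effect: iid Poisson(exp(intercept))
  sim0 <- genCountsAndAttributes(
    cfg, nIndividuals = 200, nNights = 1,
    betas = c(intercept = 2, rank = 0, sexfemale = 0, age = 0,
              centrality = 0, relatives = 0), sigmaId = 0)
  expect_lt(abs(mean(sim0$data$count) - exp(2)),
            3 * sqrt(exp(2) / 200))
  expect_lt(abs(var(sim0$data$count) / mean(sim0$data$count) - 1), 0.35)

  # sex effect: female/male rate ratio near exp(beta)
  simS <- genCountsAndAttributes(
    cfg, nIndividuals = 4000, nNights = 1,
    betas = c(intercept = 3, rank = 0, sexfemale = -1.909, age = 0,
              centrality = 0, relatives = 0), sigmaId = 0)
  d <- simS$data
  ratio <- mean(d$count[d$sex == "female"]) / mean(d$count[d$sex == "male"])
  expect_lt(abs(ratio - exp(-1.909)), 0.03)

  # a large random intercept produces overdispersion
  simOD <- genCountsAndAttributes(
    cfg, nIndividuals = 300, nNights = 1,
    betas = c(intercept = 2, rank = 0, sexfemale = 0, age = 0,
              centrality = 0, relatives = 0), sigmaId = 1)
  expect_gt(var(simOD$data$count) / mean(simOD$data$count), 2)
})

test_that("weather series honor range contracts and autocorrelation", {
  cfg <- simConfig(seed = 31)
  wx <- genWeather(cfg, nHours = 500)
  expect_true(all(wx$humidity >= 0 & wx$humidity <= 100))
  expect_true(all(wx$precipitation >= 0))
  expect_true(all(wx$wind_direction >= 0 & wx$wind_direction < 360))
  expect_true(all(wx$surface_wind_speed >= 0))
  expect_equal(wx$surface_wind_speed,
               sqrt(wx$zonal_wind^2 + wx$meridional_wind^2))

  ac <- stats::acf(wx$temperature, plot = FALSE)$acf[2]
  expect_lt(abs(ac - cfg$weather$phi), 0.1)
})

test_that("writeSimulation exports readable CSV files", {
  dir <- withr::local_tempdir()
  cfg <- simConfig(seed = 41, nIndividuals = 8, sampleRate = 4000,
                   dutySeconds = 2)
  out <- writeSimulation(cfg, dir)
  files <- c("calls.csv", "behaviors.csv", "proximity.csv", "focal.csv",
             "agonistic.csv", "pedigree.csv", "attributes.csv",
             "weather.csv")
  expect_true(all(file.exists(file.path(dir, files))))
  calls <- read.csv(file.path(dir, "calls.csv"))
  expect_equal(nrow(calls), nrow(out$night$calls))
})
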