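test_that("vif matches closed forms and flags perfect collinearity", {
  n <- 200
  set.seed(61)
  x1 <- rnorm(n); x2 <- rnorm(n)
  v <- vif(data.frame(x1, x2))
  expect_equal(unname(v), c(1, 1), tolerance = 0.1)  # orthogonal in expectation

  expect_warning(vd <- vif(data.frame(x1, x2 = x1)), "perfect collinearity")
  expect_true(all(is.infinite(vd)))

  # correlated pair: VIF = 1 / (1 - r^2) exactly, by construction
  x2 <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(n)
  r2 <- cor(x1, x2)^2
  v2 <- vif(data.frame(x1, x2))
  expect_equal(unname(v2), rep(1 / (1 - r2), 2), tolerance = 1e-10)

  expect_error(vif(data.frame(x1)), "at least 2")
})

test_that("vif agrees with the car reference implementation", {
  skip_if_not_installed("car")
  set.seed(62)
  d <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  d$b <- d$b + 0.6 * d$a
  d$y <- rnorm(100)
  want <- car::vif(lm(y ~ a + b + c, data = d))
  expect_equal(vif(d[c("a", "b", "c")]), want, tolerance = 1e-8)
})

test_that("the count GLMM recovers a known configuration and validates input", {
  cfg <- simConfig(seed = 8)
  sim <- genCountsAndAttributes(cfg, nIndividuals = 40, nNights = 20)
  tab <- fitCountGlmm(sim$data, standardize = FALSE)
  expect_equal(tab$term,
               c("(Intercept)", "rank", "sexfemale", "age", "centrality",
                 "relatives"))
  truth <- unname(sim$truth$betas)
  expect_equal(tab$estimate, truth, tolerance = 0.4)
  expect_true(all(attr(tab, "vif") < 5))
  expect_true(attr(tab, "random"))

  bad <- sim$data
  bad$count[1] <- 1.5
  expect_error(fitCountGlmm(bad), "non-integer counts")
})

test_that("single-observation data degrade to a GLM with a warning", {
  cfg <- simConfig(seed = 9)
  sim <- genCountsAndAttributes(cfg, nIndividuals = 60, nNights = 1)
  expect_warning(tab <- fitCountGlmm(sim$data, standardize = FALSE),
                 "random intercept")
  expect_false(attr(tab, "random"))
  expect_equal(nrow(tab), 6)
})

test_that("an exposure offset leaves slope estimates unchanged", {
  cfg <- simConfig(seed = 10)
  sim <- genCountsAndAttributes(cfg, nIndividuals = 30, nNights = 10)
  d <- sim$data
  d$hours <- 13
  base <- fitCountGlmm(d, standardize = FALSE)
  offs <- fitCountGlmm(d, standardize = FALSE, offsetLog = "hours")
  slopes <- base$term != "(Intercept)"
  expect_equal(offs$estimate[slopes], base$estimate[slopes],
               tolerance = 1e-4)
  expect_equal(offs$estimate[1], base$estimate[1] - log(13),
               tolerance = 1e-4)
})

test_that("the weather GAM recovers planted effects and their shapes", {
  cfg <- simConfig(seed = 11)
  wx <- genWeather(cfg, nHours = 400)
  coup <- list(
    meridional_wind = function(v) 2.5 * exp(-(v / 1.5)^2),
    temperature_humidity = function(t, h) 1.5 * (-(t - 5) / 3) *
      ((h - 75) / 10) / 2
  )
  sim <- genCoupledAci(wx, coupling = coup, noiseSd = 0.3, seed = 111)
  tab <- fitAciGam(sim$aci, wx)
  expect_true("s(meridional_wind)" %in% tab$term)
  expect_true("ti(temperature,humidity)" %in% tab$term)

  # fitted partial effect of meridional wind vs truth on a grid
  m <- attr(tab, "model")
  grid <- as.data.frame(lapply(wx[, !(names(wx) %in% c("time", "hour"))],
                               function(v) rep(stats::median(v), 101)))
  grid$meridional_wind <- seq(-3, 3, length.out = 101)
  terms <- predict(m, newdata = grid, type = "terms")
  fitted <- terms[, "s(meridional_wind)"]
  truthFun <- coup$meridional_wind(grid$meridional_wind)
  expect_gt(cor(fitted, truthFun), 0.9)
  expect_gt(attr(tab, "adj_r2"), 0.5)
})

test_that("a periodic wind-direction effect is recovered with maxima near 90 and 270 degrees", {
  cfg <- simConfig(seed = 12)
  wx <- genWeather(cfg, nHours = 450)
  coup <- list(wind_direction = function(th) 1.5 * cos(2 * (th - 90) *
                                                         pi / 180))
  sim <- genCoupledAci(wx, coupling = coup, noiseSd = 0.25, seed = 112)
  tab <- fitAciGam(sim$aci, wx)
  expect_true("s(wind_direction)" %in% tab$term)
  m <- attr(tab, "model")
  grid <- as.data.frame(lapply(wx[, !(names(wx) %in% c("time", "hour"))],
                               function(v) rep(stats::median(v), 361)))
  grid$wind_direction <- 0:360
  eff <- predict(m, newdata = grid, type = "terms")[, "s(wind_direction)"]
  # local maxima of the fitted periodic smooth
  peaks <- grid$wind_direction[which(diff(sign(diff(eff))) == -2) + 1]
  expect_true(any(abs(peaks - 90) <= 15))
  expect_true(any(abs(peaks - 270) <= 15))
})

test_that("backward removal is deterministic and traces its steps", {
  cfg <- simConfig(seed = 13)
  wx <- genWeather(cfg, nHours = 250)
  sim <- genCoupledAci(wx, coupling = list(
    surface_wind_speed = function(w) -0.8 * w), seed = 113)
  t1 <- fitAciGam(sim$aci, wx)
  t2 <- fitAciGam(sim$aci, wx)
  expect_identical(t1$term, t2$term)
  expect_identical(attr(t1, "removal_trace"), attr(t2, "removal_trace"))
  expect_true(all(t1$p < 0.05))
  tr <- attr(t1, "removal_trace")
  expect_true(all(tr$p >= 0.05))
  expect_named(attr(t1, "candidate_aic"))
})

test_that("the Friedman wrapper matches the rank-sum formula and a permutation oracle", {
  # one category always largest, one always smallest, 2 blocks
  tab <- matrix(c(5, 6, 3, 2, 1, 0), nrow = 2)  # cols: big, mid, small
  got <- friedmanBehaviorTest(tab)
  expect_equal(got$statistic, 4)
  expect_equal(got$df, 2)

  # constant table: no information
  flat <- matrix(2, 3, 3)
  expect_equal(friedmanBehaviorTest(flat),
               list(statistic = 0, df = 2, p = 1))

  # statistic invariant under within-block strictly monotone transforms
  set.seed(63)
  tb <- matrix(rpois(12, 5) + seq_len(12) / 100, 4, 3)
  a <- friedmanBehaviorTest(tb)
  b <- friedmanBehaviorTest(exp(tb / 4))
  expect_equal(a$statistic, b$statistic)

  # small-table p against exhaustive within-block permutations: the
  # chi-square approximation tracks the exact p (coarsely mid-scale,
  # closely in the rejection tail)
  set.seed(64)
  for (i in 1:4) {
    rnd <- matrix(sample(0:9, 12, TRUE) + runif(12) / 10, 4, 3)
    expect_lt(abs(friedmanBehaviorTest(rnd)$p - friedmanPermOracle(rnd)),
              0.2)
  }
  strong <- matrix(c(9, 8, 9, 10, 4, 5, 4, 6, 1, 0, 2, 1), 4, 3)
  expect_lt(friedmanBehaviorTest(strong)$p, 0.05)
  expect_lt(friedmanPermOracle(strong), 0.05)

  # sleep column dropped by default, kept on request
  named <- matrix(rpois(8 * 4, 4), 8, 4,
                  dimnames = list(NULL, c("aggression", "social", "sleep",
                                          "other")))
  expect_equal(friedmanBehaviorTest(named, includeSleep = TRUE)$df, 3)
  expect_equal(friedmanBehaviorTest(named)$df, 2)
  expect_error(friedmanBehaviorTest(named[, 1:2]), "at least 3")
})
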