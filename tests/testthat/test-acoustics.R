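test_that("spectrogram frame count and degenerate inputs follow the STFT contract", {
  ps <- computeSpectrogram(rnorm(48000), 48000, frameLength = 1024,
                           hop = 512)
  expect_equal(nFrames(ps), floor((48000 - 1024) / 512) + 1)  # 92
  expect_equal(nBands(ps), 512)

  expect_error(computeSpectrogram(numeric(0), 48000), "empty audio")
  expect_error(computeSpectrogram(rnorm(100), -1), "positive")

  silent <- computeSpectrogram(rep(0, 8000), 8000, frameLength = 256,
                               hop = 128)
  expect_true(all(specPower(silent) == 0))
})

test_that("a bin-centered pure tone concentrates power in one band (rectangular window)", {
  sr <- 8000; n <- 256
  f0 <- 10 * sr / n  # exactly bin 10
  wave <- sin(2 * pi * f0 * seq_len(sr) / sr)
  ps <- computeSpectrogram(wave, sr, frameLength = n, hop = n,
                           window = "rectangular")
  p <- specPower(ps)
  peak <- apply(p, 2, which.max)
  expect_true(all(peak == 11))  # bins are 0-indexed frequencies
  offPeak <- p[-11, ]
  expect_lt(max(offPeak) / min(p[11, ]), 1e-10)
})

test_that("stereo input is downmixed by channel averaging", {
  l <- rnorm(4000); r <- rnorm(4000)
  psLR <- computeSpectrogram(cbind(l, r), 8000, frameLength = 256,
                             hop = 128)
  psM <- computeSpectrogram((l + r) / 2, 8000, frameLength = 256,
                            hop = 128)
  expect_equal(specPower(psLR), specPower(psM))
})

test_that("bandLimit keeps exactly the overlapping rows, in order", {
  m <- matrix(runif(40), 4, 10)
  ps <- PowerSpectrogram(m, freqLower = c(0, 100, 200, 300),
                         freqUpper = c(100, 200, 300, 400))
  expect_equal(specPower(bandLimit(ps, 0, 400)), m)       # identity
  half <- bandLimit(ps, 0, 200)
  expect_equal(nBands(half), 2)
  expect_equal(specPower(half), m[1:2, ])
  expect_error(bandLimit(ps, 150, 150), "fMin must be smaller")
  expect_error(bandLimit(ps, 1000, 2000), "empty band")
})

test_that("aciValue matches hand evaluations and handles degeneracies", {
  # constant spectrogram: no intensity change anywhere
  expect_identical(aciValue(matrix(5, 7, 20)), 0)
  # 1,3,1,3 alternation: three pairs, each |2|/4
  expect_equal(aciValue(matrix(c(1, 3, 1, 3), nrow = 1)), 1.5)
  # all-zero pairs contribute 0, not NaN
  expect_identical(aciValue(matrix(0, 3, 5)), 0)
  expect_error(aciValue(matrix(1, 3, 1)), "window too short")
})

test_that("ACI is scale-free, bounded, and blind to silent bands", {
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(rexp(20 * 50), 20, 50)
    a <- aciValue(m)
    expect_lt(abs(aciValue(m * runif(1, 0.001, 1000)) - a) / a, 1e-9)
    expect_gte(a, 0)
    expect_lte(a, 20 * 49)
    expect_equal(aciValue(rbind(m, 0)), a)  # silent band is inert
  }
})

test_that("classical total-intensity normalization differs and is scale-free", {
  m <- matrix(c(1, 3, 1, 3), nrow = 1)
  expect_equal(aciValue(m, normalization = "total"), 6 / 8)
  set.seed(4)
  r <- matrix(rexp(100), 5, 20)
  expect_equal(aciValue(r * 7, normalization = "total"),
               aciValue(r, normalization = "total"))
})

test_that("aciWindows partitions, sums, and drops short remainders", {
  m <- matrix(rexp(10 * 60), 10, 60)
  ps <- PowerSpectrogram(m, timeStep = 1)
  one <- aciWindows(ps, windowS = 60)
  expect_equal(nrow(one$windows), 1)
  expect_equal(one$total, one$windows$aci)
  expect_equal(one$total, aciValue(m))

  # two identical windows: additivity
  ps2 <- PowerSpectrogram(cbind(m, m), timeStep = 1)
  two <- aciWindows(ps2, windowS = 60)
  expect_equal(nrow(two$windows), 2)
  expect_equal(two$total, 2 * aciValue(m))

  # 60 + 60 + trailing 1 column: remainder dropped
  ps3 <- PowerSpectrogram(cbind(m, m, m[, 1]), timeStep = 1)
  expect_equal(nrow(aciWindows(ps3, windowS = 60)$windows), 2)
  # trailing partial window of >= 2 columns is kept
  ps4 <- PowerSpectrogram(cbind(m, m[, 1:2]), timeStep = 1)
  expect_equal(nrow(aciWindows(ps4, windowS = 60)$windows), 2)

  expect_error(aciWindows(ps, windowS = 1.5), "twice the frame step")
})

test_that("windowed ACI equals the per-window nested-loop oracle", {
  set.seed(21)
  m <- matrix(rexp(15 * 90), 15, 90)
  ps <- PowerSpectrogram(m, timeStep = 1)
  got <- aciWindows(ps, windowS = 30)
  want <- vapply(0:2, function(w) naiveAci(m[, w * 30 + 1:30]), numeric(1))
  expect_equal(got$windows$aci, want, tolerance = 1e-12)
  expect_equal(got$total, sum(want))
})

test_that("hourlyAci groups by window start hour and averages", {
  t0 <- as.POSIXct("2023-11-02 22:50:00", tz = "UTC")
  win <- data.frame(window_index = 1:3,
                    start_time = t0 + c(0, 600, 1200),  # 22:50 23:00 23:10
                    aci = c(1, 2, 3))
  h <- hourlyAci(win)
  expect_equal(h$hour, c(22, 23))
  expect_equal(h$aci, c(1, 2.5))
  expect_equal(h$n_windows, c(1L, 2L))

  same <- data.frame(window_index = 1:3, start_time = t0 + c(0, 60, 120),
                     aci = c(1, 2, 3))
  expect_equal(hourlyAci(same)$aci, 2)
  expect_equal(nrow(hourlyAci(win[0, ])), 0)
})

test_that("PowerSpectrogram validity rejects malformed objects", {
  expect_error(PowerSpectrogram(matrix(-1, 2, 3)), "nonnegative")
  expect_error(PowerSpectrogram(matrix(1, 2, 3), freqLower = c(0, 50),
                                freqUpper = c(100, 150)), "overlap")
  expect_error(PowerSpectrogram(matrix(1, 2, 3), timeStep = 0), "positive")
})
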