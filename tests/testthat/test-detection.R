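test_that("normalized autocorrelation matches the brute-force oracle", {
  set.seed(10)
  for (rep in 1:100) {
    L <- sample(80:200, 1)
    x <- rnorm(L)
    K <- min(40L, L - 1L)
    expect_equal(normalizedAutocorrelation(x, K), bruteForcePsi(x, K),
                 tolerance = 1e-12)
  }
  expect_error(normalizedAutocorrelation(rnorm(30), 30), "smaller")
})

test_that("autocorrelation reflects perfect periodicity", {
  x <- rep(sin(2 * pi * (0:19) / 20), 10)  # integer period 20
  psi <- normalizedAutocorrelation(x, 40)
  expect_gte(psi[20], 0.99)
  # zero-energy sub-windows give zero
  z <- c(rnorm(50), rep(0, 150))
  expect_equal(normalizedAutocorrelation(z, 190)[160], 0)
})

test_that("first zero crossing applies the sign-change rule", {
  expect_identical(firstZeroCrossing(c(0.8, 0.2, -0.1, 0.3)), 3L)
  # product exactly zero satisfies <= 0
  expect_identical(firstZeroCrossing(c(0.9, 0.0, 0.4)), 2L)
  expect_identical(firstZeroCrossing(c(0.9, 0.8, 0.7), fallbackK0 = 1L), 1L)
  expect_error(firstZeroCrossing(numeric(0)), "empty")
})

test_that("harmonic ratio separates periodic frames from noise", {
  fs <- 1000
  params <- harmonicRatioParams()
  expect_equal(round(params@maxLagS * fs), 40)  # 40 samples = 40 ms

  tone <- sin(2 * pi * 100 * (0:1999) / fs)
  expect_gte(harmonicRatio(tone, params, fs), 0.99)
  # amplitude scale invariance
  expect_equal(harmonicRatio(tone, params, fs),
               harmonicRatio(100 * tone, params, fs), tolerance = 1e-12)
  # degenerate frame
  expect_identical(harmonicRatio(rep(2, 100), params, fs), 0)

  # Monte-Carlo null: white-noise frames stay far below the 0.4 threshold
  set.seed(20)
  etaNull <- replicate(1000, harmonicRatio(rnorm(2000), params, fs))
  expect_lt(quantile(etaNull, 0.95), 0.4)
})

test_that("added noise does not increase the expected harmonic ratio", {
  fs <- 1000
  params <- harmonicRatioParams()
  tone <- sin(2 * pi * 120 * (0:1999) / fs)
  set.seed(30)
  meanEta <- vapply(c(0, 0.5, 2), function(sdn)
    mean(replicate(30, harmonicRatio(tone + rnorm(2000, sd = sdn),
                                     params, fs))), numeric(1))
  expect_true(all(diff(meanEta) <= 1e-3))
})

test_that("segment detection isolates flight bouts", {
  wasp <- fixtureWaspAnalog()  # stationary 0-6 s, flapping 6-10 s
  segs <- detectSegments(wasp)
  info <- segmentInfo(segs)
  expect_gt(nrow(info), 0)
  expect_true(all(info$startS >= 5))
  # the flapping interval is covered by retained frames
  covered <- unlist(lapply(info$startS, function(s) seq(s, s + 2, by = 0.5)))
  expect_true(all(seq(6, 10, by = 0.5) %in% covered))
  expect_true(all(info$etaHr > 0.4 & info$etaHr <= 1))

  # noise-only recording yields no segments at the default threshold
  quiet <- synthesizeRecording(defaultSpeciesProfiles()[[1]],
                               sceneConfig(durationS = 12, seed = 9), "S0")
  expect_length(detectSegments(quiet), 0L)

  # threshold 0 retains every frame
  all <- detectSegments(wasp, hrParams = harmonicRatioParams(threshold = 0))
  expect_length(all, 11L)  # floor((12.001-2)/1)+1
})

test_that("multi-duration scanning respects exclusivity", {
  pr <- speciesProfile("Apis mellifera", fwMean = 240, fwSd = 8,
                       harmonicEnvelope = 1, snrDb = 25)
  rec <- synthesizeRecording(pr, sceneConfig(
    durationS = 12, boutSchedule = list(c(3, 5)), seed = 13), "S1")
  out <- resegmentDurations(rec, durations = c(2, 1), exclusive = TRUE)
  i2 <- segmentInfo(out[["2"]])
  i1 <- segmentInfo(out[["1"]])
  expect_gt(nrow(i2), 0)
  # no 1 s segment overlaps a region claimed at 2 s
  if (nrow(i1)) {
    for (r in seq_len(nrow(i1))) {
      s <- i1$startS[r]; e <- s + 1
      overlaps <- any(s < i2$startS + 2 & e > i2$startS)
      expect_false(overlaps)
    }
  }
  expect_error(resegmentDurations(rec, durations = c(1, 2)), "descending")
})

test_that("overlapped scanning of a 4 s bout yields 39 windows at 0.2 s", {
  pr <- speciesProfile("Apis mellifera", fwMean = 240, fwSd = 8,
                       harmonicEnvelope = 1, bodyMotionAmp = 0, snrDb = 30)
  rec <- synthesizeRecording(pr, sceneConfig(
    durationS = 4, boutSchedule = list(c(0, 4)), seed = 17,
    inclusiveEndpoints = FALSE), "S1")
  out <- resegmentDurations(rec, durations = 0.2, exclusive = FALSE)
  expect_identical(length(out[["0.2"]]), 39L)  # floor((4-0.2)/0.1)+1

  # 0.1 s windows still dominate the maximum lag K = 40 < L = 100
  out2 <- resegmentDurations(rec, durations = 0.1, exclusive = FALSE)
  expect_gt(length(out2[["0.1"]]), 0)
  expect_error(resegmentDurations(rec, durations = 0.04), "maximum lag")
})
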