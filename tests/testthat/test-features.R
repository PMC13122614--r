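test_that("the default registry defines exactly 70 uniquely named features", {
  reg <- defaultFeatureRegistry()
  nm <- featureNames(reg)
  expect_length(nm, 70L)
  expect_identical(anyDuplicated(nm), 0L)
  # every feature named in the importance analysis is present
  expect_true(all(c("mfccDelta1", "WT_F0", "PEF_F0", "NCF_F0",
                    "HarmonicRatio", "bandPower_100_150",
                    "bandPower_250_300", "bandPower_300_350",
                    "bandPower_400_450", "mfcc0", "mfcc1", "mfcc3", "mfcc7",
                    "mfccDelta5", "mfccDelta7", "mfccDeltaDelta0",
                    "mfccDeltaDelta1", "mfccDeltaDelta3", "mfccDeltaDelta5",
                    "mfccDeltaDelta7") %in% nm))
  # a mis-sized registry is a configuration error
  expect_error(featureRegistry(reg@entries[1:69, ], expectedTotal = 70L),
               "70")
})

test_that("MFCC dynamics distinguish stationary from chirped signals", {
  fs <- 1000
  t <- (0:1999) / fs
  tone <- sin(2 * pi * 150 * t)
  m <- mfccBlock(tone, melSpec(), fs)
  expect_length(m, 42L)
  deltas <- m[grepl("^mfccDelta[0-9]", names(m))]
  expect_lt(max(abs(deltas)), 1e-6)  # no spectral change over time

  # amplitude scaling moves only the 0th cepstral coefficient
  m5 <- mfccBlock(5 * tone, melSpec(), fs)
  expect_equal(m5[paste0("mfcc", 1:13)], m[paste0("mfcc", 1:13)],
               tolerance = 1e-9)
  expect_equal(unname(m5["mfcc0"] - m["mfcc0"]), 2 * sqrt(26) * log(5),
               tolerance = 1e-6)

  # a chirped fundamental produces strictly larger delta magnitudes
  phase <- 2 * pi * cumsum(seq(120, 200, length.out = 2000)) / fs
  chirp <- sin(phase)
  mc <- mfccBlock(chirp, melSpec(), fs)
  expect_gt(mean(abs(mc[grepl("^mfccDelta[0-9]", names(mc))])),
            mean(abs(deltas)) + 1e-4)

  expect_error(mfccBlock(numeric(2), melSpec(), fs), "subframe")
})

test_that("all three fundamental estimators recover synthetic wingbeats", {
  fs <- 1000
  x <- cleanSegment(150, c(1, 0.5, 0.25), snrDb = 20, seed = 1)
  expect_equal(estimateF0Pef(x, fs = fs), 150, tolerance = 2.5 / 150)
  expect_equal(estimateF0Wavelet(x, fs = fs), 150, tolerance = 2.5 / 150)
  expect_equal(estimateF0Ncf(x, fs = fs), 150, tolerance = 2.5 / 150)

  # pure fundamental only
  x1 <- cleanSegment(220, 1, snrDb = 25, seed = 2)
  expect_equal(estimateF0Pef(x1, fs = fs), 220, tolerance = 0.02)
  expect_equal(estimateF0Wavelet(x1, fs = fs), 220, tolerance = 0.02)

  # integer-period case is exact for the correlation estimator
  tone <- cos(2 * pi * 200 * (0:1999) / fs)
  expect_equal(estimateF0Ncf(tone, fs = fs), 200, tolerance = 1e-3)

  # white noise is flagged missing by all three
  set.seed(4)
  noise <- rnorm(2000)
  expect_true(is.na(estimateF0Pef(noise, fs = fs)))
  expect_true(is.na(estimateF0Wavelet(noise, fs = fs)))
  expect_true(is.na(estimateF0Ncf(noise, fs = fs)))
})

test_that("the estimators agree on clean segments across the band", {
  fs <- 1000
  for (fw in c(100, 150, 210, 260, 300)) {
    x <- cleanSegment(fw, 1, snrDb = 25, seed = round(fw))
    ests <- c(estimateF0Pef(x, fs = fs), estimateF0Wavelet(x, fs = fs),
              estimateF0Ncf(x, fs = fs))
    expect_false(anyNA(ests))
    expect_lt(max(ests) - min(ests), 5)
  }
})

test_that("band-power ratios partition the periodogram", {
  fs <- 1000
  tone <- sin(2 * pi * 120 * (0:1999) / fs)
  bp <- bandPowerRatios(tone, fs = fs)
  expect_named(bp, sprintf("bandPower_%d_%d", seq(50, 450, 50),
                           seq(100, 500, 50)))
  expect_gt(bp["bandPower_100_150"], 0.95)
  expect_lt(max(bp[names(bp) != "bandPower_100_150"]), 0.02)
  expect_lte(sum(bp), 1)
  expect_equal(bp, bandPowerRatios(7 * tone, fs = fs), tolerance = 1e-12)

  two <- sin(2 * pi * 120 * (0:1999) / fs) + sin(2 * pi * 320 * (0:1999) / fs)
  bp2 <- bandPowerRatios(two, fs = fs)
  expect_equal(unname(bp2["bandPower_100_150"]), 0.5, tolerance = 0.05)
  expect_equal(unname(bp2["bandPower_300_350"]), 0.5, tolerance = 0.05)
})

test_that("spectral descriptors match their defining formulas", {
  fs <- 1000
  set.seed(5)
  noise <- rnorm(2000)
  tone <- sin(2 * pi * 180 * (0:1999) / fs)

  dn <- spectralTemporalBlock(noise, fs)
  dt <- spectralTemporalBlock(tone, fs)
  expect_length(dn, 15L)
  expect_gt(dn["spectralFlatness"], 0.25)   # broadband
  expect_lt(dt["spectralFlatness"], 1e-3)   # line spectrum
  expect_equal(unname(dt["spectralCentroid"]), 180, tolerance = 0.01)
  expect_equal(unname(dt["peakFrequency"]), 180, tolerance = 0.01)

  # centroid/spread against an independent periodogram-moment oracle
  w <- 0.5 * (1 - cos(2 * pi * (0:1999) / 1999))
  P <- abs(fft(noise * w))[1:1001]^2
  f <- (0:1000) * fs / 2000
  cen <- sum(f * P) / sum(P)
  spr <- sqrt(sum((f - cen)^2 * P) / sum(P))
  expect_equal(unname(dn["spectralCentroid"]), cen, tolerance = 1e-9)
  expect_equal(unname(dn["spectralSpread"]), spr, tolerance = 1e-9)
})

test_that("feature extraction emits complete deterministic vectors", {
  wasp <- fixtureWaspAnalog()
  segs <- detectSegments(wasp)
  se <- extractFeatures(segs)
  M <- SummarizedExperiment::assay(se, "features")
  expect_identical(nrow(M), 70L)
  expect_identical(ncol(M), length(segs))
  expect_true(all(is.finite(M)))
  # the detection statistic is carried into the feature vector
  expect_equal(unname(M["HarmonicRatio", ]), segmentInfo(segs)$etaHr)
  # determinism
  se2 <- extractFeatures(segs)
  expect_identical(M, SummarizedExperiment::assay(se2, "features"))

  # ordering of F0 features follows the species' true fundamentals
  lo <- simulateSegmentCohort(2, defaultSpeciesProfiles()["Bombus terrestris"],
                              snrDb = 20, seed = 6)
  hi <- simulateSegmentCohort(2, defaultSpeciesProfiles()["Vespula vulgaris"],
                              snrDb = 20, seed = 6)
  Mlo <- SummarizedExperiment::assay(extractFeatures(lo$segments))
  Mhi <- SummarizedExperiment::assay(extractFeatures(hi$segments))
  for (f0 in c("PEF_F0", "WT_F0", "NCF_F0"))
    expect_true(all(Mhi[f0, ] > Mlo[f0, ]))
})

test_that("silent or noise segments are imputed, not dropped", {
  set.seed(8)
  info <- data.frame(recordingId = "r", subjectId = "s", species = "x",
                     startS = 0, durationS = 2, etaHr = 0.1,
                     stringsAsFactors = FALSE)
  segs <- new("SegmentSet", samples = list(rnorm(2000)), info = info,
              fs = 1000)
  M <- SummarizedExperiment::assay(extractFeatures(segs))
  expect_true(all(is.finite(M)))
  # all three estimators fail on noise -> imputed at the search floor
  expect_equal(unname(M["NCF_F0", 1]), 50)
  expect_equal(unname(M["PEF_F0", 1]), 50)
  expect_equal(unname(M["WT_F0", 1]), 50)
})
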