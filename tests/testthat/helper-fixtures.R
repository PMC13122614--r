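# Shared, lazily-built fixtures. Everything is generated in code under
# fixed seeds; heavier objects are cached for reuse across test files.

.fixtures <- new.env(parent = emptyenv())

# Standard 5-species cohort: 4 subjects per species, one 60 s recording each.
fixtureCohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generateCohort(defaultSpeciesProfiles(),
                                       nSubjectsPerSpecies = 4, seed = 11)
  .fixtures$cohort
}

# Wasp-analog recording: stationary 0-6 s, flapping 6-10 s, 12 s capture.
fixtureWaspAnalog <- function() {
  if (is.null(.fixtures$wasp)) {
    pr <- defaultSpeciesProfiles()[["Vespula vulgaris"]]
    sc <- sceneConfig(durationS = 12, boutSchedule = list(c(6, 10)),
                      seed = 7)
    .fixtures$wasp <- synthesizeRecording(pr, sc, "WASP")
  }
  .fixtures$wasp
}

# A clean 2 s wingbeat segment (preprocessed real channel) with known fw.
cleanSegment <- function(fw, amplitudes = c(1, 0.5, 0.25), snrDb = 20,
                         durationS = 2, fs = 1000, seed = 1) {
  stopifnot(length(amplitudes) * fw < fs / 2)
  wing <- synthesizeWingbeat(wingbeatSpec(fw, amplitudes), fs, durationS)
  noisePower <- sum(amplitudes^2) / 10^(snrDb / 10)
  noise <- withr::with_seed(seed, complex(
    real = rnorm(length(wing), sd = sqrt(noisePower / 2)),
    imaginary = rnorm(length(wing), sd = sqrt(noisePower / 2))))
  x <- highpassFilter(normalizeIQ(wing + noise), filterSpec(), fs)
  Re(x)
}

# Independent brute-force oracle for the normalized autocorrelation.
bruteForcePsi <- function(x, K) {
  L <- length(x)
  psi <- numeric(K)
  for (k in seq_len(K)) {
    num <- 0; e1 <- 0; e2 <- 0
    for (n in seq_len(L - k)) {
      num <- num + x[n] * x[n + k]
      e1 <- e1 + x[n]^2
      e2 <- e2 + x[n + k]^2
    }
    psi[k] <- if (e1 == 0 || e2 == 0) 0 else num / sqrt(e1 * e2)
  }
  psi
}

# Toy tree models reused by attribution tests and the oracle-equivalence
# acceptance check.
fixtureToyBoost <- function() {
  if (is.null(.fixtures$toyBoost)) {
    set.seed(42)
    X <- matrix(rnorm(300 * 4), 300)
    colnames(X) <- paste0("f", 1:4)
    y <- as.integer(X[, 1] + X[, 2] * X[, 3] > 0)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.3, nthread = 1, base_score = 0.5, seed = 1),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = 15, verbose = 0)
    .fixtures$toyBoost <- list(model = bst, X = X)
  }
  .fixtures$toyBoost
}

fixtureToyForest <- function() {
  if (is.null(.fixtures$toyForest)) {
    set.seed(43)
    X <- matrix(rnorm(200 * 3), 200)
    colnames(X) <- c("u", "v", "w")
    y <- factor(ifelse(X[, 1] - X[, 2] > 0, "pos", "neg"))
    rf <- ranger::ranger(x = as.data.frame(X), y = y, num.trees = 25,
                         probability = TRUE, seed = 3, num.threads = 1,
                         splitrule = "extratrees")
    .fixtures$toyForest <- list(model = rf, X = X)
  }
  .fixtures$toyForest
}
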