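# Synthetic, linearly separable feature blobs for fast cascade tests.
makeBlobs <- function(nPerSpecies = 40, nSubjects = 4, sdNoise = 0.1,
                      seed = 1) {
  tax <- taxonomyTable()
  set.seed(seed)
  rows <- lapply(seq_len(nrow(tax)), function(k) {
    X <- cbind(sep = rnorm(nPerSpecies, mean = 3 * k, sd = sdNoise),
               matrix(rnorm(nPerSpecies * 4), nPerSpecies))
    colnames(X) <- c("sep", paste0("n", 1:4))
    list(X = X,
         species = rep(tax$species[k], nPerSpecies),
         subjectId = sprintf("%s_%d", substr(tax$species[k], 1, 3),
                             rep_len(seq_len(nSubjects), nPerSpecies)))
  })
  list(X = do.call(rbind, lapply(rows, `[[`, "X")),
       species = unlist(lapply(rows, `[[`, "species")),
       subjectId = unlist(lapply(rows, `[[`, "subjectId")))
}

test_that("subject-grouped splitting prevents identity leakage", {
  info <- data.frame(
    species = rep(taxonomyTable()$species, each = 200),
    subjectId = paste0(rep(taxonomyTable()$species, each = 200), "_",
                       rep_len(rep(1:5, each = 40), 1000)))
  sp <- subjectGroupedSplit(info, testFraction = 0.2, seed = 4)
  trainSubj <- unique(info$subjectId[sp$train])
  testSubj <- unique(info$subjectId[sp$test])
  expect_length(intersect(trainSubj, testSubj), 0L)
  # 5 equal subjects per species at 20% -> exactly one subject each in test
  perSpecies <- table(info$species[sp$test])
  expect_true(all(perSpecies == 200 / 5))
  expect_length(sp$testSubjects, 5L)
  # determinism
  sp2 <- subjectGroupedSplit(info, testFraction = 0.2, seed = 4)
  expect_identical(sp, sp2)

  # a species with one subject goes to train, with a warning
  info1 <- data.frame(species = c(rep("Apis mellifera", 10),
                                  rep("Vespula vulgaris", 10)),
                      subjectId = c(rep("a1", 10), rep("v", 5),
                                    rep("w", 5)))
  expect_warning(sp1 <- subjectGroupedSplit(info1, 0.2, seed = 1),
                 "single subject")
  expect_true(all(which(info1$species == "Apis mellifera") %in% sp1$train))
})

test_that("class weights follow the inverse-frequency rule", {
  w <- computeClassWeights(rep(c("a", "b"), c(100, 50)))
  expect_equal(unname(w[c("a", "b")]), c(0.75, 1.5))
  # balanced labels get unit weights
  wb <- computeClassWeights(rep(c("a", "b", "c"), each = 30))
  expect_equal(unname(wb), rep(1, 3))
  # weights strictly decrease with class count
  wm <- computeClassWeights(rep(c("a", "b", "c"), c(10, 20, 40)))
  expect_true(all(diff(wm[c("a", "b", "c")]) < 0))
  # per-sample mean weight is one
  lab <- rep(c("a", "b", "c"), c(7, 19, 31))
  wl <- computeClassWeights(lab)
  expect_equal(mean(wl[lab]), 1)
})

test_that("the cascade trains on strata and routes predictions", {
  blobs <- makeBlobs()
  cfg <- list(nRounds = 60L, nTrees = 60L, seed = 5L)
  model <- fitCascade(blobs, config = cfg)

  pred <- predictCascade(model, blobs$X)
  # near-perfect training accuracy on separable blobs
  expect_gte(mean(pred$species == blobs$species), 0.99)

  # every prediction is a valid taxonomy path
  tax <- taxonomyTable()
  key <- paste(tax$family, tax$genus, tax$species)
  expect_true(all(paste(pred$family, pred$genus, pred$species) %in% key))

  # routing: stage-1 Vespidae finalizes as Vespula vulgaris
  vv <- pred$species == "Vespula vulgaris"
  expect_true(all(pred$genus[vv] == "Vespula" & pred$family[vv] == "Vespidae"))
  am <- pred$species == "Apis mellifera"
  expect_true(all(pred$genus[am] == "Apis" & pred$family[am] == "Apidae"))

  # seeded determinism of fit + predict
  model2 <- fitCascade(blobs, config = cfg)
  expect_identical(predictCascade(model2, blobs$X), pred)

  # missing strata are named explicitly
  apidaeOnly <- blobs$species != "Vespula vulgaris"
  expect_error(fitCascade(list(X = blobs$X[apidaeOnly, ],
                               species = blobs$species[apidaeOnly]),
                          config = cfg), "Vespidae")
  noMusc <- blobs$species != "Bombus muscorum"
  expect_error(fitCascade(list(X = blobs$X[noMusc, ],
                               species = blobs$species[noMusc]),
                          config = cfg), "Bombus muscorum")
})

test_that("evaluation reproduces hand-computed metrics", {
  # toy 2-class confusion: TP = 8, FP = 2, FN = 1 for Apis mellifera
  truth <- c(rep("Apis mellifera", 9), rep("Bombus lapidarius", 7))
  pred <- c(rep("Apis mellifera", 8), "Bombus lapidarius",
            rep("Apis mellifera", 2), rep("Bombus lapidarius", 5))
  ev <- evaluateCascade(pred, truth)
  m <- ev@metrics["Apis mellifera", ]
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 8 / 9)
  expect_equal(m$F1, 2 * (0.8 * 8 / 9) / (0.8 + 8 / 9))

  # perfect predictions
  tax <- taxonomyTable()
  evp <- evaluateCascade(tax$species, tax$species)
  expect_equal(evp@accuracy, 1)
  expect_true(all(evp@metrics$F1 == 1))
  expect_equal(unname(evp@stageAccuracy), c(1, 1, 1))

  # labels outside the taxonomy are rejected
  expect_error(evaluateCascade("Musca domestica", "Apis mellifera"),
               "taxonomy")
})

test_that("micro-averaged F1 equals accuracy on single-label data", {
  tax <- taxonomyTable()
  for (s in 1:20) {
    set.seed(s)
    truth <- sample(tax$species, 60, replace = TRUE)
    pred <- sample(tax$species, 60, replace = TRUE)
    ev <- evaluateCascade(pred, truth)
    expect_equal(ev@microF1, ev@accuracy, tolerance = 1e-12)
  }
})

test_that("cumulative confusion matrices carry finalized classes forward", {
  truth <- c("Vespula vulgaris", "Apis mellifera", "Bombus muscorum",
             "Bombus terrestris")
  pred <- c("Vespula vulgaris", "Bombus lapidarius", "Apis mellifera",
            "Bombus terrestris")
  ev <- evaluateCascade(pred, truth)
  expect_identical(sum(ev@confusion$species), 4L)
  expect_identical(sum(ev@confusion$genus), 4L)
  expect_identical(sum(ev@confusion$family), 4L)
  # the wasp counts as Vespidae/Vespula at every granularity
  expect_identical(unname(ev@confusion$family["Vespidae", "Vespidae"]), 1L)
  expect_identical(unname(ev@confusion$genus["Vespula", "Vespula"]), 1L)
  # family level is right for the Apis/Bombus mix-ups
  expect_identical(unname(ev@confusion$family["Apidae", "Apidae"]), 3L)
  expect_gte(ev@stageAccuracy["family"], ev@stageAccuracy["species"])
})
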