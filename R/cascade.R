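# Hierarchical family -> genus -> species classifier cascade.
#
# Stage 1: gradient-boosted trees, Vespidae vs Apidae, on all rows; stage-1
# Vespidae is finalized as Vespula vulgaris. Stage 2: gradient-boosted
# trees, Apis vs Bombus, trained on Apidae rows; Apis is finalized as Apis
# mellifera. Stage 3: extremely-randomized trees over the three Bombus
# species, trained on Bombus rows. Class weights penalize minority-class
# errors; the train/test split is grouped by subject so no individual
# appears on both sides.

#' Taxonomy of the five focal species
#'
#' @return data.frame with columns \code{species}, \code{genus},
#'   \code{family}: Vespidae/Vespula/vulgaris, Apidae/Apis/mellifera and
#'   Apidae/Bombus/\{lapidarius, muscorum, terrestris\}.
#' @export
taxonomyTable <- function() {
  data.frame(
    species = c("Apis mellifera", "Bombus lapidarius", "Bombus muscorum",
                "Bombus terrestris", "Vespula vulgaris"),
    genus = c("Apis", "Bombus", "Bombus", "Bombus", "Vespula"),
    family = c("Apidae", "Apidae", "Apidae", "Apidae", "Vespidae"),
    stringsAsFactors = FALSE)
}

taxonomyLookup <- function(labels, to = c("genus", "family"),
                           taxonomy = taxonomyTable()) {
  to <- match.arg(to)
  bad <- setdiff(unique(labels), taxonomy$species)
  if (length(bad))
    stop("labels outside the taxonomy: ", paste(bad, collapse = ", "))
  taxonomy[[to]][match(labels, taxonomy$species)]
}

#' Subject-grouped train/test split
#'
#' Partitions samples by subject so that no subject contributes to both
#' sides. Within each species, subjects are randomly ordered under the seed
#' and assigned to the test side until the realized test sample fraction is
#' as close to \code{testFraction} as the group sizes allow (at least one
#' subject when the species has two or more). A species with a single
#' subject is assigned entirely to training with a warning.
#'
#' @param info data.frame with columns \code{species} and \code{subjectId}
#'   (e.g. \code{segmentInfo()} or \code{colData} of a feature table).
#' @param testFraction target fraction of samples in the test set.
#' @param seed RNG seed; the same seed reproduces the split.
#' @return list with integer row indices \code{train} and \code{test} and
#'   the character vector \code{testSubjects}.
#' @export
subjectGroupedSplit <- function(info, testFraction = 0.2, seed = 1) {
  stopifnot(testFraction > 0, testFraction < 1)
  info <- as.data.frame(info)
  testSubjects <- character(0)
  for (sp in sort(unique(info$species))) {
    rows <- info$species == sp
    counts <- table(info$subjectId[rows])
    if (length(counts) < 2) {
      warning("species '", sp, "' has a single subject; assigned to train")
      next
    }
    ord <- withSeed(seed + sum(utf8ToInt(sp)) %% 1000L,
                    sample(names(counts)))
    cum <- cumsum(as.numeric(counts[ord])) / sum(counts)
    k <- which.min(abs(cum - testFraction))
    k <- max(1L, min(k, length(ord) - 1L))  # leave at least one in train
    testSubjects <- c(testSubjects, ord[seq_len(k)])
  }
  testIdx <- which(info$subjectId %in% testSubjects)
  trainIdx <- setdiff(seq_len(nrow(info)), testIdx)
  list(train = trainIdx, test = testIdx, testSubjects = testSubjects)
}

#' Class weights for imbalanced training
#'
#' \code{weight_c = total / (n_classes * count_c)}, i.e. inversely
#' proportional to class frequency and with per-sample mean weight 1.
#'
#' @param labels vector of class labels.
#' @return named numeric vector of per-class weights.
#' @export
computeClassWeights <- function(labels) {
  counts <- table(labels)
  w <- length(labels) / (length(counts) * as.numeric(counts))
  names(w) <- names(counts)
  w
}

fitBoostedStage <- function(X, yFactor, weights, config) {
  y01 <- as.integer(yFactor) - 1L  # alphabetical level order: first level = 0
  d <- xgboost::xgb.DMatrix(X, label = y01, weight = weights)
  params <- list(objective = "binary:logistic",
                 max_depth = config$maxDepth, eta = config$eta,
                 nthread = 1, base_score = 0.5, seed = config$seed)
  xgboost::xgb.train(params = params, data = d, nrounds = config$nRounds,
                     verbose = 0)
}

#' Fit the hierarchical cascade
#'
#' Trains the three stages on true labels: stage 1 on all rows (family),
#' stage 2 on Apidae rows (genus), stage 3 on Bombus rows (species), each
#' with class weights computed on its own training labels. Fully seeded and
#' deterministic.
#'
#' @param train a \code{SummarizedExperiment} from [extractFeatures()]
#'   (training rows only), or a list with \code{X} (samples x features
#'   matrix) and \code{species} labels.
#' @param config list of hyperparameters; defaults: 300 boosting rounds,
#'   depth 6, learning rate 0.1, 300 extra-trees, seed 1.
#' @return A [CascadeModel-class].
#' @export
fitCascade <- function(train, config = list()) {
  cfg <- utils::modifyList(list(nRounds = 300L, maxDepth = 6L, eta = 0.1,
                                nTrees = 300L, seed = 1L), config)
  dat <- asCascadeData(train)
  X <- dat$X; species <- dat$species
  taxonomy <- taxonomyTable()
  family <- taxonomyLookup(species, "family", taxonomy)
  genus <- taxonomyLookup(species, "genus", taxonomy)

  for (lev in list(c("family", "Apidae"), c("family", "Vespidae")))
    if (!any(family == lev[2]))
      stop("training data has no rows for ", lev[1], " stratum '", lev[2], "'")
  apidae <- family == "Apidae"
  if (length(unique(genus[apidae])) < 2)
    stop("training data has no rows for genus stratum 'Apis' or 'Bombus'")
  bombus <- genus == "Bombus"
  if (length(unique(species[bombus])) < 3)
    stop("training data is missing a Bombus species stratum: ",
         paste(setdiff(taxonomy$species[taxonomy$genus == "Bombus"],
                       unique(species[bombus])), collapse = ", "))

  famF <- factor(family, levels = sort(unique(taxonomy$family)))
  w1 <- computeClassWeights(famF)
  m1 <- fitBoostedStage(X, famF, as.numeric(w1[as.character(famF)]), cfg)

  genF <- factor(genus[apidae], levels = c("Apis", "Bombus"))
  w2 <- computeClassWeights(genF)
  m2 <- fitBoostedStage(X[apidae, , drop = FALSE], genF,
                        as.numeric(w2[as.character(genF)]),
                        utils::modifyList(cfg, list(seed = cfg$seed + 1L)))

  spLevels <- sort(taxonomy$species[taxonomy$genus == "Bombus"])
  spF <- factor(species[bombus], levels = spLevels)
  w3 <- computeClassWeights(spF)
  df3 <- as.data.frame(X[bombus, , drop = FALSE])
  m3 <- ranger::ranger(x = df3, y = spF, num.trees = cfg$nTrees,
                       splitrule = "extratrees", probability = TRUE,
                       case.weights = as.numeric(w3[as.character(spF)]),
                       seed = cfg$seed + 2L, num.threads = 1)

  new("CascadeModel", stage1 = m1, stage2 = m2, stage3 = m3,
      featureNames = colnames(X),
      classLevels = list(family = levels(famF), genus = levels(genF),
                         species3 = spLevels),
      classWeights = list(family = w1, genus = w2, species3 = w3),
      taxonomy = taxonomy, config = cfg)
}

# Accept either a SummarizedExperiment or a list(X, species, subjectId).
asCascadeData <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    X <- t(SummarizedExperiment::assay(x, "features"))
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    list(X = X, species = cd$species, subjectId = cd$subjectId, info = cd)
  } else {
    stopifnot(is.list(x), !is.null(x$X))
    list(X = as.matrix(x$X), species = x$species, subjectId = x$subjectId,
         info = as.data.frame(x[setdiff(names(x), "X")]))
  }
}

#' Predict with the cascade
#'
#' Routes each sample through the hierarchy: stage-1 Vespidae is finalized
#' as \emph{Vespula vulgaris} without invoking later stages; stage-2 Apis
#' maps to \emph{Apis mellifera}; remaining samples get the stage-3 Bombus
#' species. Probability ties break towards the alphabetically first class.
#' Every returned triple is a valid taxonomy path.
#'
#' @param model a [CascadeModel-class].
#' @param newdata feature matrix (samples x features), data.frame, or a
#'   \code{SummarizedExperiment} from [extractFeatures()].
#' @return data.frame with columns \code{family}, \code{genus},
#'   \code{species}.
#' @export
predictCascade <- function(model, newdata) {
  X <- if (methods::is(newdata, "SummarizedExperiment"))
    t(SummarizedExperiment::assay(newdata, "features"))
  else as.matrix(newdata)
  X <- X[, model@featureNames, drop = FALSE]
  n <- nrow(X)
  family <- character(n); genus <- character(n); species <- character(n)

  p1 <- predict(model@stage1, X)  # P(second level) = P(Vespidae)
  vesp <- p1 > 0.5                # tie (0.5) -> alphabetical first (Apidae)
  family[vesp] <- "Vespidae"; genus[vesp] <- "Vespula"
  species[vesp] <- "Vespula vulgaris"

  if (any(!vesp)) {
    family[!vesp] <- "Apidae"
    p2 <- predict(model@stage2, X[!vesp, , drop = FALSE])  # P(Bombus)
    isBombus <- p2 > 0.5          # tie -> Apis (alphabetical)
    idxA <- which(!vesp)[!isBombus]
    genus[idxA] <- "Apis"; species[idxA] <- "Apis mellifera"
    idxB <- which(!vesp)[isBombus]
    if (length(idxB)) {
      genus[idxB] <- "Bombus"
      p3 <- predict(model@stage3,
                    as.data.frame(X[idxB, , drop = FALSE]))$predictions
      # which.max takes the first (alphabetical) column on exact ties
      species[idxB] <- model@classLevels$species3[apply(p3, 1, which.max)]
    }
  }
  data.frame(family = family, genus = genus, species = species,
             stringsAsFactors = FALSE)
}

confusionMatrix <- function(truth, pred, levels) {
  table(factor(truth, levels = levels), factor(pred, levels = levels))
}

#' Evaluate cascade predictions
#'
#' Builds cumulative confusion matrices at family, genus and species
#' granularity (classes finalized in earlier stages are carried forward into
#' the later matrices), per-species precision/recall/F1 with
#' \code{F1 = 2 * precision * recall / (precision + recall)}, the overall
#' accuracy (confusion-matrix trace over total) and the micro-averaged F1,
#' which equals accuracy for single-label data.
#'
#' @param predictions data.frame from [predictCascade()], or a character
#'   vector of species predictions.
#' @param truth character vector of true species labels.
#' @return A [CascadeEvaluation-class].
#' @export
evaluateCascade <- function(predictions, truth) {
  predSpecies <- if (is.data.frame(predictions)) predictions$species
                 else as.character(predictions)
  stopifnot(length(predSpecies) == length(truth))
  taxonomy <- taxonomyTable()
  bad <- setdiff(unique(predSpecies), taxonomy$species)
  if (length(bad))
    stop("predicted labels outside the taxonomy: ",
         paste(bad, collapse = ", "))
  truthFam <- taxonomyLookup(truth, "family", taxonomy)
  truthGen <- taxonomyLookup(truth, "genus", taxonomy)
  predFam <- taxonomyLookup(predSpecies, "family", taxonomy)
  predGen <- taxonomyLookup(predSpecies, "genus", taxonomy)

  cFam <- confusionMatrix(truthFam, predFam, sort(unique(taxonomy$family)))
  cGen <- confusionMatrix(truthGen, predGen, sort(unique(taxonomy$genus)))
  cSp <- confusionMatrix(truth, predSpecies, taxonomy$species)

  tp <- diag(cSp)
  fp <- colSums(cSp) - tp
  fn <- rowSums(cSp) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  metrics <- data.frame(precision = precision, recall = recall, F1 = f1,
                        row.names = taxonomy$species)

  n <- length(truth)
  acc <- sum(tp) / n
  # micro-averaged F1 from pooled TP/FP/FN
  microP <- sum(tp) / (sum(tp) + sum(fp))
  microR <- sum(tp) / (sum(tp) + sum(fn))
  microF1 <- 2 * microP * microR / (microP + microR)

  new("CascadeEvaluation",
      confusion = list(family = cFam, genus = cGen, species = cSp),
      metrics = metrics, accuracy = acc,
      stageAccuracy = c(family = sum(diag(cFam)) / n,
                        genus = sum(diag(cGen)) / n, species = acc),
      microF1 = microF1, nTest = as.integer(n))
}

#' Duration-sweep experiment
#'
#' Runs detect -> extract -> split -> fit -> evaluate for each window
#' duration on a cohort of recordings, with exclusive segment use across
#' durations (every region of signal contributes only at the longest
#' duration for which it qualifies) and a single subject-grouped split
#' shared by all durations. Reports per-duration sample counts, overall
#' species accuracy and per-species F1.
#'
#' @param recordings list of [RadarRecording-class] objects.
#' @param durations window durations (s), sorted descending.
#' @param hrParams,filterSpec,registry pipeline parameters.
#' @param testFraction,seed split and model seeds.
#' @param config cascade hyperparameters (see [fitCascade()]).
#' @param exclusive passed to [resegmentDurations()].
#' @return data.frame with one row per duration (durationS, nTrain, nTest,
#'   accuracy and one F1 column per species); the full
#'   [CascadeEvaluation-class] objects are attached as
#'   \code{attr(x, "evaluations")}.
#' @export
durationSweep <- function(recordings,
                          durations = c(2, 1, 0.8, 0.6, 0.4, 0.2, 0.1),
                          hrParams = harmonicRatioParams(),
                          filterSpec = wingbeatRadar::filterSpec(),
                          registry = defaultFeatureRegistry(),
                          testFraction = 0.2, seed = 1, config = list(),
                          exclusive = TRUE) {
  perRec <- lapply(recordings, resegmentDurations, durations = durations,
                   hrParams = hrParams, filterSpec = filterSpec,
                   exclusive = exclusive)
  byDur <- lapply(as.character(durations), function(d)
    combineSegments(lapply(perRec, `[[`, d)))
  names(byDur) <- as.character(durations)

  # one subject split shared by every duration, from pooled segment counts
  pooled <- do.call(rbind, lapply(byDur, segmentInfo))
  split <- subjectGroupedSplit(pooled, testFraction, seed)
  testSubjects <- split$testSubjects

  taxonomy <- taxonomyTable()
  rows <- list(); evals <- list()
  for (d in as.character(durations)) {
    segs <- byDur[[d]]
    info <- segmentInfo(segs)
    res <- data.frame(durationS = as.numeric(d), nTrain = NA_integer_,
                      nTest = NA_integer_, accuracy = NA_real_)
    for (sp in taxonomy$species)
      res[[paste0("F1_", gsub(" ", "_", sp))]] <- NA_real_
    if (length(segs)) {
      se <- extractFeatures(segs, registry)
      isTest <- info$subjectId %in% testSubjects
      res$nTrain <- sum(!isTest); res$nTest <- sum(isTest)
      fitOk <- tryCatch({
        model <- fitCascade(se[, !isTest],
                            config = utils::modifyList(list(seed = seed),
                                                       config))
        pred <- predictCascade(model, se[, isTest])
        ev <- evaluateCascade(pred, info$species[isTest])
        evals[[d]] <- ev
        res$accuracy <- ev@accuracy
        for (sp in taxonomy$species)
          res[[paste0("F1_", gsub(" ", "_", sp))]] <- ev@metrics[sp, "F1"]
        TRUE
      }, error = function(e) {
        message("duration ", d, " s: ", conditionMessage(e))
        FALSE
      })
    }
    rows[[d]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "evaluations") <- evals
  out
}
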