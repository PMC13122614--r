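# Shapley feature attributions.
#
# Two routes: an exact enumeration oracle for any prediction function over
# at most 12 features, and a fast closed-form interventional algorithm for
# tree ensembles. Both use the interventional value function: the value of
# a coalition S is the mean model output with in-S features taken from the
# explained instance and the rest from background rows. Because each tree
# leaf corresponds to an axis-aligned box, the coalition game restricted to
# one (leaf, background row) pair is an unanimity-style indicator game with
# a closed-form Shapley value, making the tree route exact as well; the
# enumeration oracle validates it on small models.

#' Exact Shapley attributions by enumeration
#'
#' Enumerates all \code{2^m} coalitions of the explained features. The
#' value of a coalition is the mean of \code{predictFn} over hybrid rows
#' built from the instance (in-coalition features) and each background row
#' (the rest). Guarded to at most 12 features.
#'
#' @param predictFn function taking a numeric matrix (rows = samples) and
#'   returning a numeric vector of model outputs.
#' @param instance named numeric vector (or 1-row matrix) to explain.
#' @param background numeric matrix of background rows (same columns).
#' @param features character vector of features to attribute (default: all
#'   columns); others are always taken from the instance.
#' @return An [AttributionResult-class] with one row.
#' @export
exactShapley <- function(predictFn, instance, background, features = NULL) {
  if (is.matrix(instance)) instance <- instance[1, ]
  background <- as.matrix(background)
  if (is.null(names(instance))) names(instance) <- colnames(background)
  if (is.null(features)) features <- colnames(background)
  m <- length(features)
  if (m > 12) stop("exact enumeration is limited to 12 features (2^12 coalitions)")
  nb <- nrow(background)

  # all coalitions as an (2^m x m) logical matrix
  coal <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  colnames(coal) <- features
  nC <- nrow(coal)

  # hybrid rows: for each coalition, nb rows
  base <- background[rep(seq_len(nb), times = nC), , drop = FALSE]
  fixed <- setdiff(colnames(background), features)
  if (length(fixed))
    base[, fixed] <- matrix(instance[fixed], nrow(base), length(fixed),
                            byrow = TRUE)
  for (j in seq_len(m)) {
    rows <- rep(coal[, j], each = nb)
    base[rows, features[j]] <- instance[features[j]]
  }
  preds <- predictFn(base)
  v <- colMeans(matrix(preds, nrow = nb))  # coalition values

  key <- coal %*% 2^(seq_len(m) - 1)      # coalition index lookup
  vByKey <- numeric(nC); vByKey[key + 1] <- v
  sizes <- rowSums(coal)
  fact <- factorial(0:m)
  phi <- numeric(m); names(phi) <- features
  for (j in seq_len(m)) {
    without <- !coal[, j]
    s <- sizes[without]
    w <- fact[s + 1] * fact[m - s] / fact[m + 1]
    vS <- vByKey[key[without] + 1]
    vSi <- vByKey[key[without] + 2^(j - 1) + 1]
    phi[j] <- sum(w * (vSi - vS))
  }
  fullRow <- matrix(instance[colnames(background)], 1,
                    dimnames = list(NULL, colnames(background)))
  new("AttributionResult", values = matrix(phi, 1,
                                           dimnames = list(NULL, features)),
      baseValues = vByKey[1], predictions = predictFn(fullRow)[1],
      featureNames = features)
}

# ---------------------------------------------------------------------------
# Tree extraction: canonical leaf-box representation
# ---------------------------------------------------------------------------

# Each tree becomes a list of leaves; a leaf is a list(value, feat, lo, hi)
# where feat indexes featureNames and the half-open side of the (lo, hi)
# box depends on the library's split convention:
#   xgboost: left branch is x < split  -> membership lo <= x < hi
#   ranger:  left branch is x <= split -> membership lo < x <= hi

extractTreesXgb <- function(model, featureNames) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
  valueCol <- if ("Gain" %in% names(dt)) "Gain" else "Quality"
  # snap parsed thresholds back to the exact float32 values the booster uses
  dt$Split <- as.numeric(roundToFloat32(as.matrix(dt$Split)))
  nFeat <- length(featureNames)
  lapply(split(dt, dt$Tree), function(tr) {
    id2row <- stats::setNames(seq_len(nrow(tr)), tr$ID)
    leaves <- list()
    recurse <- function(row, lo, hi) {
      if (tr$Feature[row] == "Leaf") {
        keep <- which(is.finite(lo) | is.finite(hi))
        leaves[[length(leaves) + 1]] <<- list(
          value = tr[[valueCol]][row], feat = keep,
          lo = lo[keep], hi = hi[keep])
        return(invisible())
      }
      f <- match(tr$Feature[row], featureNames)
      s <- tr$Split[row]
      hiL <- hi; hiL[f] <- min(hiL[f], s)
      recurse(id2row[[tr$Yes[row]]], lo, hiL)       # x < split
      loR <- lo; loR[f] <- max(loR[f], s)
      recurse(id2row[[tr$No[row]]], loR, hi)        # x >= split
    }
    recurse(which(tr$Node == 0), rep(-Inf, nFeat), rep(Inf, nFeat))
    leaves
  })
}

extractTreesRanger <- function(model, featureNames, class) {
  nFeat <- length(featureNames)
  lapply(seq_len(model$num.trees), function(i) {
    tr <- ranger::treeInfo(model, i)
    # treeInfo mangles class labels through make.names when building columns
    predCol <- c(paste0("pred.", class), make.names(paste0("pred.", class)))
    predCol <- intersect(predCol, names(tr))[1]
    if (is.na(predCol))
      stop("class '", class, "' not found in the forest")
    leaves <- list()
    recurse <- function(row, lo, hi) {
      if (tr$terminal[row]) {
        keep <- which(is.finite(lo) | is.finite(hi))
        leaves[[length(leaves) + 1]] <<- list(
          value = tr[[predCol]][row], feat = keep,
          lo = lo[keep], hi = hi[keep])
        return(invisible())
      }
      f <- match(tr$splitvarName[row], featureNames)
      s <- tr$splitval[row]
      hiL <- hi; hiL[f] <- min(hiL[f], s)
      recurse(tr$leftChild[row] + 1L, lo, hiL)      # x <= split
      loR <- lo; loR[f] <- max(loR[f], s)
      recurse(tr$rightChild[row] + 1L, loR, hi)     # x > split
    }
    recurse(1L, rep(-Inf, nFeat), rep(Inf, nFeat))
    leaves
  })
}

# membership of values v in the leaf interval for one feature
inInterval <- function(v, lo, hi, rightClosed) {
  if (rightClosed) v > lo & v <= hi else v >= lo & v < hi
}

# Interventional Shapley values for a list of leaf-box trees.
# X: instances to explain (n x p); B: background rows (m x p).
# Returns list(values = n x p matrix, base = scalar).
treeShapleyValues <- function(trees, X, B, rightClosed, scale = 1) {
  n <- nrow(X); m <- nrow(B); p <- ncol(X)
  maxRQ <- 64L
  lf <- lgamma(seq_len(2L * maxRQ + 2L))  # lf[k] = log((k-1)!)
  phi <- matrix(0, n, p, dimnames = list(NULL, colnames(X)))
  base <- 0
  fx <- numeric(n)
  for (tree in trees) {
    for (leaf in tree) {
      k <- length(leaf$feat)
      if (k == 0L) { base <- base + leaf$value; fx <- fx + leaf$value; next }
      # background membership per constrained feature: m x k
      okB <- vapply(seq_len(k), function(j)
        inInterval(B[, leaf$feat[j]], leaf$lo[j], leaf$hi[j], rightClosed),
        logical(m))
      if (m == 1L) okB <- matrix(okB, nrow = 1L)
      nBIn <- rowSums(okB)
      base <- base + leaf$value * sum(nBIn == k) / m
      for (i in seq_len(n)) {
        okX <- vapply(seq_len(k), function(j)
          inInterval(X[i, leaf$feat[j]], leaf$lo[j], leaf$hi[j],
                     rightClosed), logical(1))
        if (all(okX)) fx[i] <- fx[i] + leaf$value
        # per background row: r = #features needing inclusion,
        # q = #features needing exclusion, unreachable if any feature
        # fails for both sources
        rCnt <- as.integer((!okB) %*% okX)
        qCnt <- as.integer(okB %*% (!okX))
        dead <- as.integer((!okB) %*% (!okX)) > 0L
        live <- !dead & (rCnt + qCnt > 0L)
        if (!any(live)) next
        r <- rCnt[live]; q <- qCnt[live]
        wIn <- exp(lf[pmax(r, 1L)] + lf[q + 1L] - lf[r + q + 1L])
        wOut <- exp(lf[r + 1L] + lf[pmax(q, 1L)] - lf[r + q + 1L])
        okBlive <- okB[live, , drop = FALSE]
        for (j in seq_len(k)) {
          f <- leaf$feat[j]
          if (okX[j]) {
            sel <- !okBlive[, j]
            if (any(sel))
              phi[i, f] <- phi[i, f] + leaf$value * sum(wIn[sel]) / m
          } else {
            sel <- okBlive[, j]
            if (any(sel))
              phi[i, f] <- phi[i, f] - leaf$value * sum(wOut[sel]) / m
          }
        }
      }
    }
  }
  list(values = phi * scale, base = base * scale, fx = fx * scale)
}

#' Fast exact attributions for a tree-ensemble stage
#'
#' Computes interventional Shapley attributions for a gradient-boosted
#' ensemble (attributing the log-odds margin) or an
#' extremely-randomized-trees probability forest (attributing the
#' probability of \code{class}) by closed-form evaluation over the leaf
#' boxes of every tree. Agrees with [exactShapley()] on the same value
#' function to numerical precision.
#'
#' @param stage an \code{xgb.Booster}, a \code{ranger} probability forest,
#'   or a [CascadeModel-class] (pick the stage with \code{stageName}).
#' @param X matrix of instances to explain (samples x features).
#' @param background matrix of background rows.
#' @param class for probability forests: the class whose probability is
#'   attributed (default: first class).
#' @param stageName when \code{stage} is a cascade:
#'   \code{"family"}, \code{"genus"} or \code{"species"}.
#' @return An [AttributionResult-class].
#' @export
treeAttributions <- function(stage, X, background, class = NULL,
                             stageName = c("family", "genus", "species")) {
  if (methods::is(stage, "CascadeModel")) {
    stageName <- match.arg(stageName)
    stage <- switch(stageName, family = stage@stage1, genus = stage@stage2,
                    species = stage@stage3)
  }
  X <- as.matrix(X); background <- as.matrix(background)
  if (inherits(stage, "xgb.Booster")) {
    trees <- extractTreesXgb(stage, colnames(X))
    # the booster compares features in float32; mirror that here so box
    # membership matches the model's own routing at split boundaries
    res <- treeShapleyValues(trees, roundToFloat32(X),
                             roundToFloat32(background),
                             rightClosed = FALSE)
  } else if (inherits(stage, "ranger")) {
    if (is.null(class)) class <- stage$forest$levels[1]
    trees <- extractTreesRanger(stage, colnames(X), class)
    res <- treeShapleyValues(trees, X, background, rightClosed = TRUE,
                             scale = 1 / stage$num.trees)
  } else stop("unsupported stage model of class ", class(stage)[1])
  new("AttributionResult", values = res$values,
      baseValues = rep(res$base, nrow(X)), predictions = res$fx,
      featureNames = colnames(X))
}

#' Attribute cascade decisions
#'
#' For each explained row, attributions are taken from the stage that
#' finalized its predicted label: stage 1 (family margin) for rows
#' predicted Vespidae, stage 2 (genus margin) for Apis, and stage 3 (the
#' predicted Bombus species' probability) otherwise.
#'
#' @param model a [CascadeModel-class].
#' @param X feature matrix or \code{SummarizedExperiment} of rows to
#'   explain.
#' @param background background feature matrix (e.g. 100 seeded training
#'   rows).
#' @return list with \code{values} (matrix rows x features),
#'   \code{species} (finalizing predictions) and \code{stage} (character).
#' @export
cascadeAttributions <- function(model, X, background) {
  if (methods::is(X, "SummarizedExperiment"))
    X <- t(SummarizedExperiment::assay(X, "features"))
  if (methods::is(background, "SummarizedExperiment"))
    background <- t(SummarizedExperiment::assay(background, "features"))
  X <- as.matrix(X)[, model@featureNames, drop = FALSE]
  background <- as.matrix(background)[, model@featureNames, drop = FALSE]
  pred <- predictCascade(model, X)
  vals <- matrix(0, nrow(X), ncol(X), dimnames = list(NULL, colnames(X)))
  stage <- character(nrow(X))
  grp <- list(
    family = pred$species == "Vespula vulgaris",
    genus = pred$species == "Apis mellifera",
    species = pred$genus == "Bombus")
  for (g in names(grp)) {
    idx <- which(grp[[g]])
    if (!length(idx)) next
    stage[idx] <- g
    if (g == "species") {
      for (sp in unique(pred$species[idx])) {
        sel <- idx[pred$species[idx] == sp]
        a <- treeAttributions(model@stage3, X[sel, , drop = FALSE],
                              background, class = sp)
        vals[sel, ] <- attributionValues(a)
      }
    } else {
      st <- if (g == "family") model@stage1 else model@stage2
      a <- treeAttributions(st, X[idx, , drop = FALSE], background)
      vals[idx, ] <- attributionValues(a)
    }
  }
  list(values = vals, species = pred$species, stage = stage)
}

#' Rank features by mean absolute attribution
#'
#' @param attributions an [AttributionResult-class], the list returned by
#'   [cascadeAttributions()], or a plain attribution matrix.
#' @param labels optional per-row grouping (e.g. predicted species) for
#'   per-class rankings.
#' @param top number of features to keep (the full list if larger than the
#'   feature count).
#' @return data.frame with \code{feature} and \code{meanAbs}, ordered
#'   descending; with \code{labels}, one extra column of mean |attribution|
#'   per group.
#' @export
rankFeatures <- function(attributions, labels = NULL, top = 20) {
  M <- if (methods::is(attributions, "AttributionResult"))
    attributionValues(attributions)
  else if (is.list(attributions) && !is.null(attributions$values))
    attributions$values
  else as.matrix(attributions)
  imp <- colMeans(abs(M))
  ord <- order(imp, decreasing = TRUE)
  ord <- ord[seq_len(min(top, length(ord)))]
  out <- data.frame(feature = colnames(M)[ord], meanAbs = imp[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    for (g in sort(unique(labels)))
      out[[make.names(g)]] <-
        colMeans(abs(M[labels == g, , drop = FALSE]))[ord]
  }
  rownames(out) <- NULL
  out
}
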