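test_that("exact Shapley satisfies the axioms", {
  set.seed(50)
  bg <- matrix(rnorm(20 * 3), 20, dimnames = list(NULL, c("x1", "x2", "x3")))
  inst <- c(x1 = 1.5, x2 = -0.5, x3 = 2)

  # null player: a model ignoring x3 attributes it zero
  f12 <- function(M) M[, "x1"] * 2 + sin(M[, "x2"])
  a <- exactShapley(f12, inst, bg)
  expect_equal(unname(attributionValues(a)[1, "x3"]), 0)

  # linearity: for f = x1 + x2 and a single background row, phi_k = x_k - b_k
  b1 <- bg[1, , drop = FALSE]
  add <- function(M) M[, "x1"] + M[, "x2"]
  al <- exactShapley(add, inst, b1)
  expect_equal(unname(attributionValues(al)[1, c("x1", "x2")]),
               unname(inst[c("x1", "x2")] - b1[1, c("x1", "x2")]))

  # efficiency: base + sum(phi) = f(instance) for an arbitrary model
  g <- function(M) M[, "x1"] * M[, "x2"] + exp(M[, "x3"] / 3)
  ag <- exactShapley(g, inst, bg)
  expect_equal(baseValues(ag) + sum(attributionValues(ag)),
               unname(g(matrix(inst, 1,
                               dimnames = list(NULL, names(inst))))),
               tolerance = 1e-9)

  # symmetry: exchangeable features with equal values get equal shares
  sym <- function(M) M[, "x1"] + M[, "x2"] + M[, "x1"] * M[, "x2"]
  bgSym <- bg; bgSym[, "x2"] <- bgSym[, "x1"]
  asym <- exactShapley(sym, c(x1 = 1, x2 = 1, x3 = 0), bgSym)
  expect_equal(unname(attributionValues(asym)[1, "x1"]),
               unname(attributionValues(asym)[1, "x2"]), tolerance = 1e-12)

  # combinatorial guard
  big <- matrix(rnorm(26), 2, 13,
                dimnames = list(NULL, paste0("f", 1:13)))
  expect_error(exactShapley(function(M) rowSums(M), big[1, ], big), "12")
})

test_that("tree attributions match exact enumeration on a boosted toy", {
  toy <- fixtureToyBoost()
  bg <- toy$X[1:7, ]
  inst <- toy$X[8:57, ]
  ta <- treeAttributions(toy$model, inst, bg)
  pf <- function(M) predict(toy$model, M, outputmargin = TRUE)
  worst <- 0
  for (i in seq_len(nrow(inst))) {
    ex <- exactShapley(pf, inst[i, ], bg)
    worst <- max(worst, max(abs(attributionValues(ta)[i, ] -
                                  attributionValues(ex))))
  }
  expect_lt(worst, 1e-6)
  # additivity against the booster's own margins
  expect_equal(baseValues(ta) + rowSums(attributionValues(ta)), pf(inst),
               tolerance = 1e-5)
})

test_that("tree attributions match exact enumeration on an extra-trees toy", {
  toy <- fixtureToyForest()
  bg <- toy$X[1:6, ]
  inst <- toy$X[7:26, ]
  ta <- treeAttributions(toy$model, inst, bg, class = "pos")
  pf <- function(M)
    predict(toy$model, as.data.frame(M))$predictions[, "pos"]
  for (i in seq_len(nrow(inst))) {
    ex <- exactShapley(pf, inst[i, ], bg)
    expect_equal(attributionValues(ta)[i, ], attributionValues(ex)[1, ],
                 tolerance = 1e-6)
  }
  # duplicating background rows leaves the mean-based values unchanged
  ta2 <- treeAttributions(toy$model, inst, rbind(bg, bg), class = "pos")
  expect_equal(attributionValues(ta2), attributionValues(ta),
               tolerance = 1e-12)
})

# Cascade over synthetic features in which only one named column separates
# the species.
makeF0Cohort <- function(seed = 1, n = 50) {
  tax <- taxonomyTable()
  set.seed(seed)
  X <- cbind(NCF_F0 = rep(c(240, 160, 200, 120, 300), each = n) +
               rnorm(5 * n, sd = 4),
             matrix(rnorm(5 * n * 5), 5 * n))
  colnames(X)[-1] <- paste0("noise", 1:5)
  list(X = X, species = rep(tax$species, each = n),
       subjectId = rep(sprintf("s%02d", 1:10), length.out = 5 * n))
}

test_that("rankings surface the informative feature", {
  cohort <- makeF0Cohort(seed = 2)
  cfg <- list(nRounds = 50L, nTrees = 50L, seed = 1L)
  model <- fitCascade(cohort, config = cfg)
  bg <- cohort$X[seq(1, 250, by = 10), ]
  att <- cascadeAttributions(model, cohort$X[seq(5, 250, by = 10), ], bg)
  rk <- rankFeatures(att)
  expect_identical(rk$feature[1], "NCF_F0")

  # per-class columns are present when labels are supplied
  rk2 <- rankFeatures(att, labels = att$species, top = 100)
  expect_identical(nrow(rk2), 6L)  # full list when top > feature count

  # permuting the informative column away destroys its rank
  permuted <- cohort
  set.seed(3)
  permuted$X[, "NCF_F0"] <- sample(permuted$X[, "NCF_F0"])
  modelP <- fitCascade(permuted, config = cfg)
  attP <- cascadeAttributions(modelP, permuted$X[seq(5, 250, by = 10), ],
                              permuted$X[seq(1, 250, by = 10), ])
  rkP <- rankFeatures(attP)
  expect_gt(which(rkP$feature == "NCF_F0"), 1L)
  expect_lt(rkP$meanAbs[rkP$feature == "NCF_F0"],
            rk$meanAbs[rk$feature == "NCF_F0"])
})

test_that("top features are stable across model seeds", {
  cohort <- makeF0Cohort(seed = 4)
  top1 <- character(5)
  for (s in 1:5) {
    model <- fitCascade(cohort, config = list(nRounds = 40L, nTrees = 40L,
                                              seed = s))
    att <- cascadeAttributions(model, cohort$X[seq(5, 250, by = 10), ],
                               cohort$X[seq(1, 250, by = 10), ])
    top1[s] <- rankFeatures(att)$feature[1]
  }
  expect_true(all(top1 == "NCF_F0"))
})

test_that("cascade attributions follow the finalizing stage", {
  cohort <- makeF0Cohort(seed = 5)
  model <- fitCascade(cohort, config = list(nRounds = 40L, nTrees = 40L,
                                            seed = 2L))
  X <- cohort$X[seq(2, 250, by = 25), ]
  att <- cascadeAttributions(model, X, cohort$X[seq(1, 250, by = 10), ])
  expect_identical(dim(att$values), dim(X))
  expect_identical(att$stage[att$species == "Vespula vulgaris"],
                   rep("family", sum(att$species == "Vespula vulgaris")))
  expect_identical(att$stage[att$species == "Apis mellifera"],
                   rep("genus", sum(att$species == "Apis mellifera")))
  bombus <- !att$species %in% c("Vespula vulgaris", "Apis mellifera")
  expect_true(all(att$stage[bombus] == "species"))
})
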