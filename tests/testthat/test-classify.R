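threeFeatures <- c("rfi", "ariaDNE", "lnOA")

test_that("well-separated classes are classified perfectly at resubstitution", {
  mns <- rbind(a = c(f1 = -5, f2 = 0), b = c(5, 0))
  tab <- generateFeatureTable(tableSpec(means = mns, sds = c(f1 = 1, f2 = 1),
                                        n_per_class = 50, seed = 1))
  fit <- qdaFit(tab, c("f1", "f2"))
  expect_equal(mean(qdaPredict(fit, tab)$label == tab$diet), 1)
})

test_that("equal priors are exactly 1/K regardless of class imbalance", {
  mns <- rbind(a = c(f1 = 0, f2 = 0), b = c(3, 3))
  tab <- generateFeatureTable(tableSpec(means = mns, sds = c(f1 = 1, f2 = 1),
                                        n_per_class = c(a = 10, b = 90),
                                        seed = 2))
  fit <- qdaFit(tab, c("f1", "f2"))
  expect_identical(fit@priors, c(0.5, 0.5))
  fitP <- qdaFit(tab, c("f1", "f2"), priors = "proportional")
  expect_equal(fitP@priors, c(0.1, 0.9))
})

test_that("under-sampled classes raise a singularity error naming the class", {
  mns <- rbind(a = c(f1 = 0, f2 = 0, f3 = 0), b = c(3, 3, 3))
  tab <- generateFeatureTable(tableSpec(means = mns,
                                        sds = c(f1 = 1, f2 = 1, f3 = 1),
                                        n_per_class = c(a = 3, b = 10),
                                        seed = 3))
  expect_error(qdaFit(tab, c("f1", "f2", "f3")), "singularity error.*'a'")
})

test_that("prediction recovers class means, breaks ties lexicographically", {
  set.seed(4)
  tab <- data.frame(diet = rep(c("beta", "alpha"), each = 30),
                    f1 = c(rnorm(30, 4), rnorm(30, -4)),
                    f2 = c(rnorm(30), rnorm(30)))
  fit <- qdaFit(tab, c("f1", "f2"))
  expect_equal(qdaPredict(fit, setNames(as.list(fit@means["alpha", ]),
                                        fit@features))$label, "alpha")
  # symmetric model: exact midpoint is a tie, resolved to the first label
  mSym <- new("DietModel", classes = c("alpha", "beta"),
              means = rbind(alpha = c(f1 = -1, f2 = 0), beta = c(1, 0)),
              covariances = list(diag(2), diag(2)), priors = c(0.5, 0.5),
              features = c("f1", "f2"))
  pr <- qdaPredict(mSym, data.frame(f1 = 0, f2 = 0))
  expect_equal(pr$label, "alpha")
  expect_equal(unname(pr$posterior[1, ]), c(0.5, 0.5))
  # posteriors always sum to one
  X <- data.frame(f1 = rnorm(20, 0, 5), f2 = rnorm(20, 0, 5))
  expect_lt(max(abs(rowSums(qdaPredict(fit, X)$posterior) - 1)), 1e-12)
  expect_error(qdaPredict(fit, data.frame(f1 = 1)), "input error")
})

test_that("predictions match the brute-force Gaussian density oracle exactly", {
  for (seed in 1:3) {
    tab <- generateFeatureTable(tableSpec("marsupial-v1", n_per_class = 12,
                                          seed = seed))
    sm <- speciesMeans(tab)
    fit <- qdaFit(sm, threeFeatures)
    mine <- qdaPredict(fit, sm)$label
    oracle <- bruteForceGaussianPredict(sm, threeFeatures, sm)
    expect_identical(mine, oracle)
  }
})

test_that("predictions and leave-one-out match MASS::qda", {
  tab <- generateFeatureTable(tableSpec("marsupial-v1", n_per_class = 15,
                                        seed = 42))
  sm <- speciesMeans(tab)
  fit <- qdaFit(sm, threeFeatures)
  ref <- MASS::qda(sm[, threeFeatures], grouping = factor(sm$diet),
                   prior = rep(1 / 4, 4))
  refPred <- predict(ref, sm[, threeFeatures])
  mine <- qdaPredict(fit, sm)
  expect_identical(mine$label, as.character(refPred$class))
  expect_lt(max(abs(mine$posterior - refPred$posterior)), 1e-10)
  refCV <- MASS::qda(sm[, threeFeatures], grouping = factor(sm$diet),
                     prior = rep(1 / 4, 4), CV = TRUE)
  loo <- looAccuracy(sm, threeFeatures)
  expect_identical(loo$predicted, as.character(refCV$class))
})

test_that("leave-one-out separates 10-sigma classes and stays near chance under the null", {
  mns <- rbind(a = c(f1 = 0, f2 = 0), b = c(10, 0), c = c(0, 10))
  tab <- generateFeatureTable(tableSpec(means = mns, sds = c(f1 = 1, f2 = 1),
                                        n_per_class = 20, seed = 5))
  expect_gte(looAccuracy(tab, c("f1", "f2"))$accuracy, 0.95)
  accs <- vapply(1:40, function(s) {
    nullTab <- generateFeatureTable(tableSpec("marsupial-v1", n_per_class = 25,
                                              separation = 0, seed = s))
    looAccuracy(nullTab, threeFeatures)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.15)
  expect_lt(mean(accs), 0.35)
})

test_that("leave-one-out performs exactly n fits and is deterministic", {
  tab <- generateFeatureTable(tableSpec("marsupial-v1", n_per_class = 14,
                                        seed = 6))
  sm <- speciesMeans(tab)
  calls <- 0L
  real <- qdaFit
  testthat::local_mocked_bindings(
    qdaFit = function(...) { calls <<- calls + 1L; real(...) },
    .package = "dentopo")
  loo <- looAccuracy(sm, threeFeatures)
  expect_identical(calls, nrow(sm))
  expect_identical(loo$predicted, looAccuracy(sm, threeFeatures)$predicted)
})

test_that("leave-one-out propagates singularity naming the held-out row", {
  mns <- rbind(a = c(f1 = 0, f2 = 0), b = c(5, 5))
  tab <- generateFeatureTable(tableSpec(means = mns, sds = c(f1 = 1, f2 = 1),
                                        n_per_class = c(a = 3, b = 10),
                                        seed = 7))
  expect_error(looAccuracy(tab, c("f1", "f2")), "held out")
})

test_that("equal-prior predictions ignore class sample-size imbalance", {
  grid <- expand.grid(f1 = seq(-2, 4, 0.5), f2 = seq(-2, 3, 0.5))
  # tripling one class's draws (same per-class distribution) barely moves the
  # equal-prior boundary, while proportional priors shift it systematically
  tab <- generateFeatureTable(tableSpec(
    means = rbind(a = c(f1 = 0, f2 = 0), b = c(2.5, 1)),
    sds = c(f1 = 1, f2 = 1), n_per_class = c(a = 40, b = 40), seed = 8))
  tab3 <- generateFeatureTable(tableSpec(
    means = rbind(a = c(f1 = 0, f2 = 0), b = c(2.5, 1)),
    sds = c(f1 = 1, f2 = 1), n_per_class = c(a = 120, b = 40), seed = 8))
  agree <- mean(qdaPredict(qdaFit(tab, c("f1", "f2")), grid)$label ==
                qdaPredict(qdaFit(tab3, c("f1", "f2")), grid)$label)
  expect_gte(agree, 0.95)
  # with proportional priors the inflated class absorbs more of the grid
  nA1 <- sum(qdaPredict(qdaFit(tab3, c("f1", "f2")), grid)$label == "a")
  nA3 <- sum(qdaPredict(qdaFit(tab3, c("f1", "f2"),
                               priors = "proportional"), grid)$label == "a")
  expect_gt(nA3, nA1)
})

test_that("clade-based cross-validation scores shared categories only", {
  mTab <- speciesMeans(generateFeatureTable(
    tableSpec("marsupial-v1", n_per_class = 16, seed = 9)))
  pTab <- speciesMeans(generateFeatureTable(
    tableSpec("primate-v1", n_per_class = 16, clade = "primate", seed = 10)))
  cv <- crossCladeValidate(mTab, pTab, threeFeatures)
  shared <- intersect(unique(pTab$diet), unique(mTab$diet))
  expect_setequal(cv$per_category$category, shared)
  # the scalar is exactly recomputable from the returned confusion table
  expect_identical(cv$shared_accuracy, sharedAccuracy(cv$confusion))
  expect_equal(cv$shared_accuracy,
               sum(cv$per_category$correct) / sum(cv$per_category$n))
  # non-shared true categories appear as rows for inspection
  expect_true(all(unique(pTab$diet) %in% rownames(cv$confusion)))
  # train = test reduces to resubstitution accuracy
  self <- crossCladeValidate(mTab, mTab, threeFeatures)
  expect_equal(self$shared_accuracy, self$training_accuracy)
  # disjoint category sets are an error
  other <- mTab
  other$diet <- paste0("x-", other$diet)
  expect_error(crossCladeValidate(mTab, other, threeFeatures), "overlap error")
})

test_that("shared-category arithmetic reproduces the published example", {
  # folivory 10/12, frugivore-insectivory 7/14, insectivory 6/7 -> 23/33
  conf <- matrix(0L, 3, 4,
                 dimnames = list(
                   true = c("folivore", "frugivore-insectivore",
                            "insectivore"),
                   predicted = c("faunivore", "folivore",
                                 "frugivore-insectivore", "insectivore")))
  conf["folivore", ] <- c(1L, 10L, 0L, 1L)
  conf["frugivore-insectivore", ] <- c(0L, 1L, 7L, 6L)
  conf["insectivore", ] <- c(0L, 0L, 1L, 6L)
  acc <- sharedAccuracy(conf, shared = c("folivore", "frugivore-insectivore",
                                         "insectivore"))
  expect_equal(acc, 23 / 33)
  expect_equal(round(100 * acc, 1), 69.7)
})
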