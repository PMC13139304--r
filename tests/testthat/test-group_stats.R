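test_that("paired comparison gates on normality and detects shifts", {
  set.seed(21)
  x <- rnorm(20)
  res <- pairedCompare(x, x + 3 + rnorm(20, 0, 0.5))
  expect_lt(res$p_value, 0.05)
  # identical multiset of normal data takes the parametric branch
  expect_equal(pairedCompare(x, sample(x))$test_name, "paired-t")
  # heavy-tailed data fails the gate
  set.seed(22)
  cx <- rcauchy(20)
  expect_equal(pairedCompare(cx, cx + rcauchy(20))$test_name,
               "wilcoxon-signed-rank")
  expect_warning(res0 <- pairedCompare(x, x), "differences are zero")
  expect_equal(res0$p_value, 1)
})

test_that("two-group comparison is calibrated and branch-faithful", {
  set.seed(23)
  rej <- mean(replicate(500, twoGroupCompare(rnorm(15), rnorm(15))$p_value < 0.05))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
  x <- rnorm(30); y <- rnorm(30) + 3   # 3 pooled SDs apart
  res <- twoGroupCompare(x, y)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$test_name, "welch-t")
  set.seed(24)
  expect_equal(twoGroupCompare(rcauchy(20), rcauchy(20))$test_name,
               "wilcoxon-rank-sum")
})

test_that("multi-group comparison picks the right branch and post-hoc pairs", {
  set.seed(25)
  vals <- c(rnorm(15), rnorm(15), rnorm(15) + 5)
  grp <- rep(c("a", "b", "c"), each = 15)
  res <- multiGroupCompare(vals, grp)
  expect_equal(res$test_name, "anova")
  expect_lt(res$p_value, 0.05)
  sig <- res$posthoc$pair[res$posthoc$p_value < 0.05]
  expect_setequal(sig, c("c-a", "c-b"))
  # skewed residuals take the rank branch with a Dunn post-hoc
  set.seed(26)
  vals2 <- c(rexp(15)^2, rexp(15)^2, rexp(15)^2 + 30)
  res2 <- multiGroupCompare(vals2, grp)
  expect_equal(res2$test_name, "kruskal-wallis")
  expect_equal(unique(res2$posthoc$method), "dunn")
  expect_true(all(c("p_value", "p_bonferroni") %in% names(res2$posthoc)))
  # n = 1 groups are excluded with a warning (the single-pair category case)
  expect_warning(res3 <- multiGroupCompare(c(vals, 1), c(grp, "d")),
                 "n = 1")
  expect_false(any(grepl("d", res3$posthoc$pair)))
})

test_that("omnibus type-I error is near nominal for the gated chain", {
  set.seed(27)
  rej <- mean(replicate(400,
    multiGroupCompare(rnorm(30), rep(c("a", "b", "c"), each = 10))$p_value < 0.05))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})

test_that("variance homogeneity preflight flags heteroscedastic groups", {
  set.seed(28)
  expect_lt(varianceHomogeneity(c(rnorm(40, 0, 1), rnorm(40, 0, 5)),
                                rep(c("a", "b"), each = 40)), 0.01)
  expect_error(varianceHomogeneity(rnorm(10), rep("a", 10)), "2 groups")
})

test_that("unit-variance PCA honours its contracts", {
  set.seed(29)
  a <- rnorm(20)
  res <- pcaScores(data.frame(a = a, b = -3 * a), c("a", "b"))
  expect_equal(res$proportion[1], 1)
  tab <- data.frame(x = rnorm(30), y = rnorm(30), z = rnorm(30))
  res2 <- pcaScores(tab)
  expect_equal(sum(res2$proportion), 1, tolerance = 1e-12)
  expect_equal(sum(res2$variance), 3, tolerance = 1e-12)
  # column order changes scores only up to sign/permutation of components
  res3 <- pcaScores(tab[, c("z", "x", "y")])
  expect_equal(sort(res2$variance), sort(res3$variance), tolerance = 1e-12)
  expect_error(pcaScores(data.frame(x = rnorm(10), y = rep(1, 10))),
               "constant column 'y'")
})

test_that("every branch decision is recorded in the result", {
  set.seed(30)
  res <- twoGroupCompare(rnorm(10), rnorm(10))
  expect_true(all(c("shapiro_x", "shapiro_y") %in% names(res$gates)))
  res2 <- multiGroupCompare(rnorm(20), rep(c("a", "b"), each = 10))
  expect_true("shapiro_residuals" %in% names(res2$gates))
})
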