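# Normality-gated univariate comparison procedures and unit-variance PCA.
# Every result records which branch fired (the Shapiro-Wilk gate at
# alpha_normality decides parametric vs rank-based), keeping the analysis
# auditable.

.shapiroP <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || diff(range(x)) == 0) return(0)  # treat as non-normal
  tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
}

.comparisonResult <- function(test_name, statistic, p_value, posthoc = NULL,
                              gates = NULL, notes = character(0)) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), posthoc = posthoc, gates = gates,
                 notes = notes),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("ComparisonResult: %s, statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Paired comparison with a normality gate
#'
#' Shapiro-Wilk is run on each group; when both pass at `alpha_normality` a
#' paired t-test is used, otherwise a Wilcoxon signed-rank test (exact null
#' for n <= 25, normal approximation with continuity correction above).
#'
#' @param x,y paired samples of equal length (>= 3).
#' @param alpha_normality gate level (default 0.05).
#' @return A `ComparisonResult` recording the branch that fired.
#' @export
pairedCompare <- function(x, y, alpha_normality = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (all(x - y == 0)) {
    warning("all paired differences are zero; p reported as 1")
    return(.comparisonResult("paired-t", statistic = 0, p_value = 1,
                             gates = c(shapiro_x = NA, shapiro_y = NA),
                             notes = "degenerate: all differences zero"))
  }
  px <- .shapiroP(x); py <- .shapiroP(y)
  gates <- c(shapiro_x = px, shapiro_y = py)
  if (px >= alpha_normality && py >= alpha_normality) {
    tt <- t.test(x, y, paired = TRUE)
    .comparisonResult("paired-t", tt$statistic, tt$p.value, gates = gates)
  } else {
    exact <- length(x) <= 25
    wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact,
                                       correct = TRUE))
    .comparisonResult("wilcoxon-signed-rank", wt$statistic, wt$p.value,
                      gates = gates)
  }
}

#' Unpaired two-group comparison with a normality gate
#'
#' Welch t-test when both groups pass the Shapiro-Wilk gate, otherwise a
#' Wilcoxon rank-sum test.
#'
#' @param x,y samples (each n >= 3).
#' @inheritParams pairedCompare
#' @return A `ComparisonResult`.
#' @export
twoGroupCompare <- function(x, y, alpha_normality = 0.05) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  px <- .shapiroP(x); py <- .shapiroP(y)
  gates <- c(shapiro_x = px, shapiro_y = py)
  if (px >= alpha_normality && py >= alpha_normality) {
    tt <- t.test(x, y, paired = FALSE, var.equal = FALSE)
    .comparisonResult("welch-t", tt$statistic, tt$p.value, gates = gates)
  } else {
    exact <- length(x) <= 25 && length(y) <= 25
    wt <- suppressWarnings(wilcox.test(x, y, paired = FALSE, exact = exact,
                                       correct = TRUE))
    .comparisonResult("wilcoxon-rank-sum", wt$statistic, wt$p.value,
                      gates = gates)
  }
}

# Dunn's rank-based post-hoc z tests with tie correction; reports unadjusted
# and Bonferroni-adjusted p-values (the display default is unadjusted).
.dunnTest <- function(values, groups) {
  g <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tieAdj <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  out <- data.frame(pair = character(0), z = numeric(0), p_value = numeric(0))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tieAdj) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    out <- rbind(out, data.frame(pair = paste(a, b, sep = " - "), z = z,
                                 p_value = 2 * pnorm(-abs(z))))
  }
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out$method <- "dunn"
  out
}

#' Multi-group comparison with a normality gate and matching post-hoc
#'
#' Shapiro-Wilk on the one-way ANOVA residuals gates ANOVA vs
#' Kruskal-Wallis. When the omnibus test is significant at 0.05, the
#' matching post-hoc runs over all pairs: Tukey HSD after ANOVA, Dunn's test
#' after Kruskal-Wallis (unadjusted and Bonferroni-adjusted p-values both
#' reported). Groups with a single observation are excluded with a warning.
#'
#' @param values numeric response.
#' @param groups group labels (same length).
#' @inheritParams pairedCompare
#' @return A `ComparisonResult`; `posthoc` is `NULL` when the omnibus test
#'   is not significant.
#' @export
multiGroupCompare <- function(values, groups, alpha_normality = 0.05) {
  stopifnot(length(values) == length(groups))
  g <- factor(as.character(groups))
  sizes <- table(g)
  drop <- names(sizes)[sizes < 2]
  notes <- character(0)
  if (length(drop)) {
    warning("excluding group(s) with n = 1: ", paste(drop, collapse = ", "))
    keep <- !(g %in% drop)
    values <- values[keep]
    g <- droplevels(g[keep])
    notes <- paste("excluded n=1 group(s):", paste(drop, collapse = ", "))
  }
  if (nlevels(g) < 2) stop("need at least 2 groups with n >= 2")
  fit <- aov(values ~ g)
  pres <- .shapiroP(stats::residuals(fit))
  gates <- c(shapiro_residuals = pres)
  if (pres >= alpha_normality) {
    an <- anova(fit)
    pval <- an[["Pr(>F)"]][1]
    posthoc <- NULL
    if (pval < 0.05) {
      tk <- TukeyHSD(fit)$g
      posthoc <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                            p_value = tk[, "p adj"], method = "tukey")
      rownames(posthoc) <- NULL
    }
    .comparisonResult("anova", an[["F value"]][1], pval, posthoc = posthoc,
                      gates = gates, notes = notes)
  } else {
    kw <- kruskal.test(values, g)
    posthoc <- if (kw$p.value < 0.05) .dunnTest(values, g) else NULL
    .comparisonResult("kruskal-wallis", kw$statistic, kw$p.value,
                      posthoc = posthoc, gates = gates, notes = notes)
  }
}

#' Levene's test for homogeneity of variance
#'
#' Mean-centred Levene's test across groups; the documented preflight that
#' motivates quadratic (rather than linear) discriminants when variances
#' differ between diet categories.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @return p-value.
#' @export
varianceHomogeneity <- function(values, groups) {
  g <- factor(as.character(groups))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  res <- car::leveneTest(values ~ g, center = mean)
  res[["Pr(>F)"]][1]
}

#' Unit-variance principal component analysis
#'
#' Columns are standardised to zero mean and unit variance (correlation-
#' matrix PCA). Variance explained is returned both in unit-variance terms
#' (summing to the number of features) and as proportions (summing to one).
#'
#' @param table data frame or matrix of observations.
#' @param features feature column names (>= 2; >= 3 rows; no missing values).
#' @return list with `scores`, `loadings`, `sdev`, `variance` and
#'   `proportion`.
#' @export
pcaScores <- function(table, features = colnames(table)) {
  X <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  stopifnot(ncol(X) >= 2, nrow(X) >= 3)
  if (anyNA(X)) stop("missing values in PCA input")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("standardisation error: constant column '",
         features[which(sds == 0)[1]], "'")
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  list(scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
       variance = pc$sdev^2, proportion = pc$sdev^2 / sum(pc$sdev^2))
}
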