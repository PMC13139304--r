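# Equal-prior quadratic discriminant analysis for diet inference, with
# leave-one-out validation and clade-based cross-validation scored on shared
# categories only. The Gaussian machinery is deliberately explicit: class
# means, unbiased class covariances, and the quadratic discriminant
# delta_k(x) = -1/2 log|Sigma_k| - 1/2 (x-mu_k)' Sigma_k^-1 (x-mu_k) + log pi_k.
# No covariance regularisation is applied by default: a class too small to
# invert errors loudly (the analysis-level remedy is to exclude the
# category), though an optional ridge is available.

#' Fit a quadratic discriminant diet model
#'
#' @param table data frame of observations (typically species means) with a
#'   class column and numeric feature columns.
#' @param features character; feature column names.
#' @param class_col class column name (default `"diet"`).
#' @param priors `"equal"` (default: 1/K per class, the convention for
#'   unbalanced comparative samples) or `"proportional"` (training
#'   frequencies).
#' @param ridge optional nonnegative ridge added as `ridge * I` to every
#'   class covariance (default 0 = off).
#' @return A [DietModel-class].
#' @export
qdaFit <- function(table, features, class_col = "diet",
                   priors = c("equal", "proportional"), ridge = 0) {
  priors <- match.arg(priors)
  miss <- setdiff(c(features, class_col), names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(table[, features, drop = FALSE])
  if (!is.numeric(X)) stop("features must be numeric")
  if (anyNA(X)) stop("missing feature values; drop or impute before fitting")
  y <- as.character(table[[class_col]])
  classes <- sort(unique(y))          # lexicographic order fixes tie-breaks
  K <- length(classes)
  p <- length(features)
  means <- matrix(NA_real_, K, p, dimnames = list(classes, features))
  covs <- vector("list", K)
  names(covs) <- classes
  for (k in seq_len(K)) {
    Xi <- X[y == classes[k], , drop = FALSE]
    if (nrow(Xi) <= p)
      stop(sprintf(paste0("singularity error: class '%s' has n = %d ",
                          "observations for p = %d features (need n >= p + 1); ",
                          "exclude the category or reduce the feature set"),
                   classes[k], nrow(Xi), p))
    means[k, ] <- colMeans(Xi)
    S <- stats::cov(Xi)               # unbiased (n - 1) covariance
    if (ridge > 0) S <- S + diag(ridge, p)
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop(sprintf("singularity error: covariance of class '%s' is singular",
                   classes[k]))
    covs[[k]] <- (S + t(S)) / 2
  }
  pri <- if (priors == "equal") rep(1 / K, K) else as.vector(table(factor(y, classes))) / length(y)
  new("DietModel", classes = classes, means = means, covariances = covs,
      priors = pri, features = features)
}

#' Predict diet with a fitted model
#'
#' Labels are the argmax of the quadratic discriminant, ties broken by
#' lexicographic class order; posteriors are the softmax of the
#' discriminants and sum to one.
#'
#' @param model a [DietModel-class].
#' @param newdata data frame (or named numeric vector) carrying the model's
#'   features; missing values are an error.
#' @return list with `label` (character vector) and `posterior` (matrix,
#'   rows = observations, columns = classes).
#' @export
qdaPredict <- function(model, newdata) {
  stopifnot(is(model, "DietModel"))
  if (is.matrix(newdata)) newdata <- as.data.frame(newdata)
  else if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  miss <- setdiff(model@features, names(newdata))
  if (length(miss)) stop("input error: missing feature(s) ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(newdata[, model@features, drop = FALSE])
  if (anyNA(X)) stop("input error: missing feature values")
  n <- nrow(X)
  K <- length(model@classes)
  delta <- matrix(NA_real_, n, K, dimnames = list(NULL, model@classes))
  for (k in seq_len(K)) {
    S <- model@covariances[[k]]
    ch <- chol(S)
    logdet <- 2 * sum(log(diag(ch)))
    dev <- sweep(X, 2, model@means[k, ], "-")
    z <- backsolve(ch, t(dev), transpose = TRUE)
    maha <- colSums(z^2)
    delta[, k] <- -0.5 * logdet - 0.5 * maha + log(model@priors[k])
  }
  lab <- model@classes[max.col(delta, ties.method = "first")]
  post <- exp(delta - apply(delta, 1, max))
  post <- post / rowSums(post)
  list(label = lab, posterior = post)
}

.confusion <- function(true, pred, trueLevels = sort(unique(true)),
                       predLevels = sort(unique(pred))) {
  tab <- table(factor(true, levels = trueLevels),
               factor(pred, levels = predLevels))
  m <- matrix(as.integer(tab), nrow = length(trueLevels),
              dimnames = list(true = trueLevels, predicted = predLevels))
  m
}

#' Shared-category accuracy from a confusion table
#'
#' Accuracy over the test rows whose TRUE category is among the training
#' categories (the confusion table's columns): correct / total over those
#' rows only.
#'
#' @param confusion counts matrix, rows = true, columns = predicted
#'   (training) categories.
#' @param shared character; the shared categories (default: row categories
#'   that are also columns).
#' @return proportion correct among shared-category rows.
#' @export
sharedAccuracy <- function(confusion,
                           shared = intersect(rownames(confusion),
                                              colnames(confusion))) {
  if (!length(shared)) stop("overlap error: no shared categories")
  correct <- sum(vapply(shared, function(k) confusion[k, k], numeric(1)))
  total <- sum(confusion[shared, , drop = FALSE])
  correct / total
}

#' Leave-one-out classification accuracy
#'
#' Each row is predicted by a model fitted on all remaining rows (exactly n
#' fits); deterministic given the table.
#'
#' @inheritParams qdaFit
#' @return list with `accuracy`, `confusion` (true x predicted counts over
#'   all classes) and `predicted` (per-row labels).
#' @export
looAccuracy <- function(table, features, class_col = "diet",
                        priors = c("equal", "proportional"), ridge = 0) {
  priors <- match.arg(priors)
  n <- nrow(table)
  y <- as.character(table[[class_col]])
  classes <- sort(unique(y))
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      qdaFit(table[-i, , drop = FALSE], features, class_col, priors, ridge),
      error = function(e)
        stop(sprintf("leave-one-out fit failed with row %d ('%s') held out: %s",
                     i, table[[class_col]][i], conditionMessage(e)), call. = FALSE))
    pred[i] <- qdaPredict(fit, table[i, , drop = FALSE])$label
  }
  conf <- .confusion(y, pred, trueLevels = classes, predLevels = classes)
  list(accuracy = mean(pred == y), confusion = conf, predicted = pred)
}

#' Clade-based cross-validation
#'
#' Fits on one clade's table and predicts the other's. Accuracy is scored on
#' shared categories only: test rows whose true category exists in the
#' training set. The full confusion table (including non-shared true
#' categories) is returned for inspection, along with per-category fractions.
#'
#' @param train,test data frames of training and test observations.
#' @inheritParams qdaFit
#' @return list with `shared_accuracy`, `confusion` (rows = all true test
#'   categories, columns = training categories), `per_category` (data frame
#'   of correct/n/fraction for each shared category), `training_accuracy`
#'   (resubstitution accuracy on the training set) and `predicted`.
#' @export
crossCladeValidate <- function(train, test, features, class_col = "diet",
                               priors = c("equal", "proportional"), ridge = 0) {
  priors <- match.arg(priors)
  model <- qdaFit(train, features, class_col, priors, ridge)
  trainClasses <- model@classes
  yTest <- as.character(test[[class_col]])
  shared <- intersect(unique(yTest), trainClasses)
  if (!length(shared))
    stop("overlap error: no diet category shared between train and test")
  pred <- qdaPredict(model, test)$label
  conf <- .confusion(yTest, pred, trueLevels = sort(unique(yTest)),
                     predLevels = trainClasses)
  perCat <- do.call(rbind, lapply(sort(shared), function(k) {
    nk <- sum(yTest == k)
    ck <- sum(yTest == k & pred == k)
    data.frame(category = k, correct = ck, n = nk, fraction = ck / nk)
  }))
  trainPred <- qdaPredict(model, train)$label
  list(shared_accuracy = sharedAccuracy(conf, shared = sort(shared)),
       confusion = conf, per_category = perCat,
       training_accuracy = mean(trainPred == as.character(train[[class_col]])),
       predicted = pred)
}
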