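#' R-squared in its sum-of-squared-errors form
#'
#' `1 - SSE / SST` with SST taken about the mean of `truth`.  0 means the
#' model predicts no better than the mean; 1 is perfect prediction; values
#' can be negative on held-out data.
#'
#' @param truth Observed numeric outcomes (not constant, length >= 2).
#' @param prediction Model predictions.
#' @return Scalar R-squared (possibly negative).
#' @export
r_squared <- function(truth, prediction) {
  stopifnot(length(truth) == length(prediction), length(truth) >= 2)
  if (var(truth) == 0) stop("truth is constant: R-squared undefined")
  1 - sum((truth - prediction)^2) / sum((truth - mean(truth))^2)
}

#' Clamp R-squared at zero
#'
#' Negative out-of-sample R-squared values are set to zero before
#' meta-modeling and benchmark reporting; the raw value is kept elsewhere.
#' Never used inside tuning losses.
#'
#' @param value Numeric.
#' @return `max(value, 0)` elementwise.
#' @export
clamp_r_squared <- function(value) pmax(value, 0)

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation with midranks, so ties contribute 1/2: the
#' probability that a randomly chosen positive case receives a higher score
#' than a randomly chosen negative case.
#'
#' @param truth Binary vector (0/1, logical, or two-level factor).
#' @param score Numeric scores or probabilities.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(truth, score) {
  y <- as.numeric(as.factor(truth)) - 1
  if (length(unique(y)) < 2) stop("both classes must be present")
  stopifnot(length(y) == length(score))
  r <- rank(score)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binomial deviance
#'
#' `-2 * sum(y log p + (1 - y) log(1 - p))`, with probabilities clipped to
#' `[1e-10, 1 - 1e-10]`.  A confident wrong prediction contributes more
#' than an uncertain wrong one.
#'
#' @param truth Binary 0/1 vector.
#' @param probability Predicted probabilities.
#' @return Nonnegative scalar deviance.
#' @export
binomial_deviance <- function(truth, probability) {
  stopifnot(length(truth) == length(probability))
  p <- pmin(pmax(probability, 1e-10), 1 - 1e-10)
  y <- as.numeric(truth)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Train-test split (80/20 protocol)
#'
#' `round(n * test_fraction)` observations go to the test set; with binary
#' labels the split is stratified so the test class ratio matches the
#' overall ratio within one observation per class.  Deterministic given the
#' seed.
#'
#' @param n Number of observations (>= 5).
#' @param test_fraction Proportion held out (default 0.20).
#' @param seed Integer seed.
#' @param labels Optional binary labels for stratification.
#' @return List with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(n, test_fraction = 0.20, seed = NULL,
                             labels = NULL) {
  stopifnot(n >= 5, test_fraction > 0, test_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n_test <- round(n * test_fraction)
  if (is.null(labels)) {
    test <- sort(sample.int(n, n_test))
  } else {
    stopifnot(length(labels) == n)
    labels <- as.character(labels)
    classes <- unique(labels)
    if (any(table(labels) < 2))
      warning("a class has fewer than 2 members; split may be degenerate")
    test <- integer(0)
    for (cl in classes) {
      idx <- which(labels == cl)
      k <- round(length(idx) * test_fraction)
      test <- c(test, sample(idx, k))
    }
    # adjust to the exact overall test size
    extra <- n_test - length(test)
    pool <- setdiff(seq_len(n), test)
    if (extra > 0) test <- c(test, sample(pool, extra))
    if (extra < 0) test <- test[seq_len(n_test)]
    test <- sort(test)
  }
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Metric report for a prediction set
#'
#' Bundles the evaluation metrics for one model on one dataset: RMSE, raw
#' and clamped R-squared for continuous outcomes; AUC and deviance for
#' binary outcomes with probability predictions.
#'
#' @param truth Observed outcomes.
#' @param prediction Predictions (probabilities for binary truth).
#' @param family `"gaussian"` or `"binomial"`.
#' @return A list of class `"metric_report"`.
#' @export
metric_report <- function(truth, prediction,
                          family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  out <- list(n = length(truth), family = family)
  if (family == "gaussian") {
    out$rmse <- sqrt(mean((truth - prediction)^2))
    out$r_squared <- r_squared(truth, prediction)
    out$r_squared_clamped <- clamp_r_squared(out$r_squared)
  } else {
    out$auc <- auc(truth, prediction)
    out$deviance <- binomial_deviance(truth, prediction)
  }
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Metric report (", x$family, ", n = ", x$n, ")\n", sep = "")
  for (nm in setdiff(names(x), c("n", "family")))
    cat(sprintf("  %-18s %.4f\n", nm, x[[nm]]))
  invisible(x)
}
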