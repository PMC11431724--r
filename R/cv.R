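#' K-fold assignment
#'
#' Fold sizes differ by at most one; with binary labels the assignment is
#' stratified so each fold's class counts are balanced to within one
#' observation.  Deterministic given the seed.
#'
#' @param n Number of observations.
#' @param nfolds Number of folds (default 10).
#' @param seed Integer seed.
#' @param labels Optional binary labels for stratification.
#' @return Integer vector of fold ids in `1..nfolds`.
#' @export
make_folds <- function(n, nfolds = 10, seed = NULL, labels = NULL) {
  stopifnot(nfolds >= 2, n >= nfolds)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) {
    folds <- sample(rep_len(seq_len(nfolds), n))
  } else {
    stopifnot(length(labels) == n)
    labels <- as.character(labels)
    if (any(table(labels) < nfolds))
      warning("a class has fewer members than folds; stratification relaxed")
    folds <- integer(n)
    # rotate the fold sequence between classes so overall sizes stay balanced
    offset <- 0
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      seq_cl <- ((seq_along(idx) - 1 + offset) %% nfolds) + 1
      folds[idx] <- sample(seq_cl)
      offset <- offset + length(idx)
    }
  }
  folds
}

#' Lambda selection from a CV curve
#'
#' `lambda_min` is the index minimizing the mean loss (ties broken toward
#' the largest lambda, i.e. the sparser model); `lambda_1se` is the largest
#' lambda whose mean loss is within one standard error of the minimum.
#' Assumes the grid is ordered from largest to smallest lambda.
#'
#' @param cvm Mean CV loss per lambda.
#' @param cvse Standard error of the fold losses per lambda.
#' @return List with integer indices `lambda_min` and `lambda_1se`.
#' @export
select_lambda <- function(cvm, cvse) {
  imin <- which(cvm == min(cvm))[1]
  thresh <- cvm[imin] + cvse[imin]
  i1se <- which(cvm <= thresh)[1]
  list(lambda_min = imin, lambda_1se = i1se)
}

#' Cross-validate a weighted-lasso path
#'
#' The lambda grid is computed once on the full data and held fixed across
#' folds.  Each fold is predicted by a path fit on its complement; fold
#' losses (RMSE for Gaussian, mean binomial deviance per observation for
#' binomial) are aggregated to per-lambda means and standard errors
#' (`sd(fold losses) / sqrt(nfolds)`), from which the lambda-min and
#' one-standard-error selections are made.  For Gaussian outcomes a pooled
#' cross-validated R-squared per lambda is also returned.
#'
#' @param x Standardized design matrix.
#' @param y Response (0/1 for binomial).
#' @param weights Penalty weights.
#' @param family `"gaussian"` or `"binomial"`.
#' @param nfolds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param stratified Stratify folds on the response (binomial; default TRUE).
#' @param foldid Optional explicit fold assignment.
#' @param ... Passed to [fit_path()] (e.g. `nlambda`, `tol`).
#' @return An object of class `"srl_cv"`: `lambda`, `cvm`, `cvse`,
#'   `lambda_min`/`lambda_1se` (indices), `cv_r2` (Gaussian), `fit` (the
#'   full-data path), `loss`.
#' @export
cross_validate <- function(x, y, weights, family = c("gaussian", "binomial"),
                           nfolds = 10, seed = NULL, stratified = TRUE,
                           foldid = NULL, ...) {
  family <- match.arg(family)
  x <- as.matrix(x)
  n <- nrow(x)
  full <- fit_path(x, y, weights, family = family, ...)
  L <- length(full$lambda)
  if (is.null(foldid)) {
    labels <- if (family == "binomial" && stratified) y else NULL
    foldid <- make_folds(n, nfolds, seed = seed, labels = labels)
  }
  nfolds <- length(unique(foldid))
  fold_loss <- matrix(NA_real_, nfolds, L)
  pred <- matrix(NA_real_, n, L)
  for (f in seq_len(nfolds)) {
    hold <- foldid == f
    if (family == "binomial" && length(unique(y[!hold])) < 2) {
      warning("fold ", f, " skipped: constant response in training complement")
      next
    }
    pf <- fit_path(x[!hold, , drop = FALSE], y[!hold], weights,
                   family = family, lambda = full$lambda, ...)
    eta <- sweep(x[hold, , drop = FALSE] %*% pf$beta, 2, pf$intercept, `+`)
    if (family == "gaussian") {
      pred[hold, ] <- eta
      fold_loss[f, ] <- sqrt(colMeans((y[hold] - eta)^2))
    } else {
      p <- plogis_clip(eta)
      pred[hold, ] <- p
      fold_loss[f, ] <- apply(p, 2, function(pp)
        binomial_deviance(y[hold], pp) / sum(hold))
    }
  }
  ok <- rowSums(is.na(fold_loss)) == 0
  if (!any(ok)) stop("no usable folds")
  cvm <- colMeans(fold_loss[ok, , drop = FALSE])
  cvse <- apply(fold_loss[ok, , drop = FALSE], 2, sd) / sqrt(sum(ok))
  sel <- select_lambda(cvm, cvse)
  cv_r2 <- if (family == "gaussian") {
    used <- !is.na(pred[, 1])
    apply(pred, 2, function(p)
      1 - sum((y[used] - p[used])^2) / sum((y[used] - mean(y[used]))^2))
  } else NULL
  structure(list(lambda = full$lambda, cvm = cvm, cvse = cvse,
                 lambda_min = sel$lambda_min, lambda_1se = sel$lambda_1se,
                 cv_r2 = cv_r2, fit = full, foldid = foldid,
                 loss = if (family == "gaussian") "rmse" else "deviance"),
            class = "srl_cv")
}

#' @export
print.srl_cv <- function(x, ...) {
  cat("Cross-validated path (", x$fit$family, ", loss = ", x$loss, ")\n",
      sep = "")
  cat(sprintf("  lambda_min: %.5g (%d nonzero)\n",
              x$lambda[x$lambda_min], x$fit$nzero[x$lambda_min]))
  cat(sprintf("  lambda_1se: %.5g (%d nonzero)\n",
              x$lambda[x$lambda_1se], x$fit$nzero[x$lambda_1se]))
  invisible(x)
}
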