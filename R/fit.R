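#' Fit a sparsity-ranked lasso model
#'
#' Top-level orchestration: preprocessing ([srl_prep()]), term expansion
#' and penalty weighting, the coordinate-descent path ([fit_path()]) and
#' K-fold cross-validation ([cross_validate()]).  With `gamma = 0`,
#' `k = 0`, `poly = 1` this reproduces a plain lasso on the main effects.
#'
#' @param data Training data frame including the target column.
#' @param target Name of the target column.
#' @param family `"auto"` (default; binary targets become binomial),
#'   `"gaussian"` or `"binomial"`.
#' @param k Maximum interaction argument (default 1: pairwise).
#' @param poly Maximum polynomial order (default 2).
#' @param filter Variance-filter mode `"nzv"`/`"zv"`/`"none"`.
#' @param gamma Penalty-weight exponent (default 0.5; 0 = plain lasso).
#' @param nfolds CV folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param rare_threshold Rare-level collapsing proportion (default 0.10).
#' @param ... Passed to [fit_path()] (e.g. `nlambda`, `lambda_min_ratio`,
#'   `tol`, `max_iter`).
#' @return An object of class `"srl"` with components `prep`, `cv`, `path`,
#'   `family`, and the selected standardized coefficient vectors
#'   `beta_min`/`beta_1se` (with intercepts `a0_min`/`a0_1se`).
#' @export
srl_fit <- function(data, target, family = c("auto", "gaussian", "binomial"),
                    k = 1, poly = 2, filter = c("nzv", "zv", "none"),
                    gamma = 0.5, nfolds = 10, seed = NULL,
                    rare_threshold = 0.10, ...) {
  family <- match.arg(family)
  filter <- match.arg(filter)
  prep <- srl_prep(data, target, k = k, poly = poly, filter = filter,
                   rare_threshold = rare_threshold, gamma = gamma)
  y <- prep$y
  if (family == "auto")
    family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial family requires a 0/1 (or two-level) target")
  cv <- cross_validate(prep$x, y, prep$weights, family = family,
                       nfolds = nfolds, seed = seed, ...)
  path <- cv$fit
  structure(list(prep = prep, cv = cv, path = path, family = family,
                 beta_min = path$beta[, cv$lambda_min],
                 beta_1se = path$beta[, cv$lambda_1se],
                 a0_min = path$intercept[cv$lambda_min],
                 a0_1se = path$intercept[cv$lambda_1se],
                 call = match.call()),
            class = "srl")
}

select_index <- function(object, lambda) {
  if (is.numeric(lambda)) return(as.integer(lambda))
  switch(match.arg(lambda, c("lambda_min", "lambda_1se")),
         lambda_min = object$cv$lambda_min,
         lambda_1se = object$cv$lambda_1se)
}

#' Predict from a fitted SRL model
#'
#' Applies the stored preprocessing recipe and term expansion to the new
#' data, then the selected coefficients.  Gaussian predictions are on the
#' response scale; binomial predictions are probabilities (inverse logit)
#' unless `type = "link"`.
#'
#' @param object An [srl_fit()] model.
#' @param newdata Data frame with the training predictor columns.
#' @param lambda `"lambda_min"` (default), `"lambda_1se"`, or a numeric
#'   index into the path.
#' @param type `"response"` (default) or `"link"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.srl <- function(object, newdata, lambda = "lambda_min",
                        type = c("response", "link"), ...) {
  type <- match.arg(type)
  idx <- select_index(object, lambda)
  xs <- bake_design(object$prep, newdata)
  predict(object$path, xs, lambda_index = idx, type = type)
}

#' Extract selected coefficients (standardized scale)
#'
#' @param object An `"srl"` model.
#' @param lambda `"lambda_min"` (default), `"lambda_1se"`, or an index.
#' @param ... Unused.
#' @return Named numeric vector including `(Intercept)`.
#' @export
coef.srl <- function(object, lambda = "lambda_min", ...) {
  idx <- select_index(object, lambda)
  c("(Intercept)" = object$path$intercept[idx], object$path$beta[, idx])
}

#' @export
print.srl <- function(x, ...) {
  cat("Sparsity-ranked lasso (", x$family, ")\n", sep = "")
  cat("  candidate terms:", nrow(x$prep$termset$terms),
      " (", length(x$prep$dropped), "filtered )\n")
  cat(sprintf("  lambda_min: %d nonzero terms; lambda_1se: %d nonzero terms\n",
              sum(x$beta_min != 0), sum(x$beta_1se != 0)))
  invisible(x)
}

#' Evaluate a fitted SRL model on new data
#'
#' @param object An `"srl"` model.
#' @param newdata Data frame including the target column.
#' @param lambda Path selection passed to [predict.srl()].
#' @return A [metric_report()].
#' @export
evaluate_srl <- function(object, newdata, lambda = "lambda_min") {
  truth <- newdata[[object$prep$target]]
  if (!is.null(object$prep$y_levels))
    truth <- as.numeric(factor(as.character(truth),
                               levels = object$prep$y_levels)) - 1
  pred <- predict(object, newdata, lambda = lambda)
  metric_report(as.numeric(truth), pred, family = object$family)
}
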