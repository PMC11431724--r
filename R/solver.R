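#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - t, 0)`: the coordinate-wise minimizer of the lasso
#' subproblem, and the mechanism that sets coefficients exactly to zero.
#'
#' @param z Numeric vector.
#' @param t Nonnegative threshold.
#' @return Numeric vector.
#' @export
soft_threshold <- function(z, t) {
  stopifnot(all(t >= 0))
  sign(z) * pmax(abs(z) - t, 0)
}

resolve_weights <- function(weights, x) {
  w <- if (inherits(weights, "penalty_weights")) weights$weights else weights
  if (!is.null(colnames(x)) && !is.null(names(w))) {
    miss <- setdiff(colnames(x), names(w))
    if (length(miss)) stop("no penalty weight for: ", paste(miss, collapse = ", "))
    w <- w[colnames(x)]
  }
  if (length(w) != ncol(x)) stop("length(weights) != ncol(x)")
  if (any(w < 0) || any(!is.finite(w))) stop("weights must be finite and >= 0")
  unname(w)
}

#' Smallest lambda with an all-null penalized fit
#'
#' `lambda_max = max over penalized j of |gradient_j at the null model| /
#' w_j`, with the gradient of the (1/2n)-scaled loss: `x_j' (y - ybar) / n`
#' for Gaussian and `x_j' (y - pbar) / n` for binomial.
#'
#' @param x Design matrix.
#' @param y Response.
#' @param weights Penalty weights ([assign_penalty_weights()] object or
#'   numeric vector aligned with `colnames(x)`).
#' @param family `"gaussian"` or `"binomial"`.
#' @return The scalar `lambda_max`.
#' @export
compute_lambda_max <- function(x, y, weights, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  x <- as.matrix(x)
  w <- resolve_weights(weights, x)
  if (all(w == 0)) stop("all penalty weights are zero: nothing to penalize")
  mu <- if (family == "gaussian") mean(y) else mean(y)
  g <- abs(drop(crossprod(x, y - mu))) / nrow(x)
  # 1 + 1e-10 guards against (g/w)*w rounding below g, which would activate
  # the top-of-path coefficient by one ulp
  max((g / w)[w > 0]) * (1 + 1e-10)
}

lambda_grid <- function(lambda_max, nlambda, lambda_min_ratio) {
  out <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                 length.out = nlambda))
  # the endpoint must be exact so the top-of-path fit is exactly null
  out[1] <- lambda_max
  out
}

#' Fit the weighted-lasso regularization path
#'
#' Minimizes `(1/2n) * loss + lambda * sum_j w_j |beta_j|` by cyclic
#' coordinate descent with warm starts over a decreasing log-spaced lambda
#' grid, where the loss is the residual sum of squares (Gaussian) or twice
#' the negative log-likelihood (binomial, solved by iteratively reweighted
#' least squares with a coordinate-descent inner loop).  The intercept is
#' always present and unpenalized.  The caller normally supplies a
#' standardized design ([standardize_columns()]); arbitrary column scales
#' are handled but penalized comparably only when standardized.
#'
#' @param x Design matrix (n x p), standardized.
#' @param y Response; must be 0/1 for the binomial family.
#' @param weights Penalty weights (object or numeric vector).
#' @param family `"gaussian"` or `"binomial"`.
#' @param nlambda Grid length (default 100).
#' @param lambda_min_ratio Smallest lambda as a fraction of `lambda_max`;
#'   defaults to 1e-3 when `n > p`, else 1e-2.
#' @param lambda Optional explicit decreasing grid (overrides the above).
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change (default 1e-8).
#' @param max_iter Sweep cap per lambda (default 10000).
#' @return An object of class `"srl_path"`: `lambda`, `beta` (p x L matrix,
#'   standardized scale), `intercept`, `nzero`, `converged`, `family`,
#'   `weights`.
#' @export
fit_path <- function(x, y, weights, family = c("gaussian", "binomial"),
                     nlambda = 100, lambda_min_ratio = NULL, lambda = NULL,
                     tol = 1e-8, max_iter = 10000) {
  family <- match.arg(family)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite inputs")
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial response must be coded 0/1")
  w <- resolve_weights(weights, x)
  if (is.null(lambda)) {
    if (is.null(lambda_min_ratio))
      lambda_min_ratio <- if (nrow(x) > ncol(x)) 1e-3 else 1e-2
    lmax <- compute_lambda_max(x, y, w, family)
    lambda <- lambda_grid(lmax, nlambda, lambda_min_ratio)
  }
  lambda <- as.numeric(lambda)
  if (is.unsorted(rev(lambda))) stop("lambda grid must be decreasing")
  fit <- if (family == "gaussian") {
    cd_gaussian_path(x, y, w, lambda, tol, max_iter)
  } else {
    cd_binomial_path(x, y, w, lambda, tol, max_iter)
  }
  if (!all(fit$converged))
    warning("coordinate descent did not converge at ",
            sum(!fit$converged), " lambda value(s)")
  rownames(fit$beta) <- colnames(x)
  structure(list(lambda = lambda, beta = fit$beta, intercept = fit$intercept,
                 nzero = fit$nzero, converged = fit$converged,
                 iters = fit$iters, family = family, weights = w,
                 term_names = colnames(x)),
            class = "srl_path")
}

#' @export
print.srl_path <- function(x, ...) {
  cat("Weighted-lasso path (", x$family, "): ", length(x$lambda),
      " lambda values, ", nrow(x$beta), " terms\n", sep = "")
  invisible(x)
}

#' Karush-Kuhn-Tucker residuals along a path
#'
#' Optimality certificate for each lambda: for inactive terms the gradient
#' must satisfy `|g_j| <= lambda * w_j`, for active terms
#' `g_j = lambda * w_j * sign(beta_j)`.  Returns the worst violation per
#' lambda; a converged fit has violations near zero.
#'
#' @param fit An [fit_path()] object.
#' @param x,y The design and response used to produce the fit.
#' @param weights Penalty weights used in the fit (defaults to those stored).
#' @return Numeric vector, one worst violation per lambda.
#' @export
kkt_residuals <- function(fit, x, y, weights = NULL) {
  x <- as.matrix(x)
  w <- if (is.null(weights)) fit$weights else resolve_weights(weights, x)
  n <- nrow(x)
  vapply(seq_along(fit$lambda), function(l) {
    b <- fit$beta[, l]
    eta <- fit$intercept[l] + drop(x %*% b)
    res <- if (fit$family == "gaussian") y - eta else y - plogis_clip(eta)
    g <- drop(crossprod(x, res)) / n
    lam <- fit$lambda[l]
    act <- b != 0
    v_in <- if (any(!act)) max(abs(g[!act]) - lam * w[!act], 0) else 0
    v_ac <- if (any(act)) max(abs(g[act] - lam * w[act] * sign(b[act]))) else 0
    max(v_in, v_ac)
  }, numeric(1))
}

plogis_clip <- function(eta, eps = 1e-10) {
  pmin(pmax(1 / (1 + exp(-eta)), eps), 1 - eps)
}

#' Predict from a raw path fit
#'
#' Linear predictor (or response-scale probability for binomial) at one
#' lambda index, for a design matrix on the same standardized scale the
#' path was fit on.  For full-pipeline prediction on raw data frames use
#' [predict.srl()].
#'
#' @param object An `"srl_path"` fit.
#' @param newx Standardized design matrix.
#' @param lambda_index Column of the path (default: last).
#' @param type `"response"` (default) or `"link"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.srl_path <- function(object, newx, lambda_index = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(lambda_index)) lambda_index <- length(object$lambda)
  newx <- as.matrix(newx)
  eta <- object$intercept[lambda_index] +
    drop(newx %*% object$beta[, lambda_index])
  if (object$family == "binomial" && type == "response") plogis_clip(eta)
  else eta
}
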