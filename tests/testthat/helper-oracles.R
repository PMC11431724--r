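# Independent oracles used to freeze expected values.  These deliberately
# share no code with the package's solver.

# Exact weighted-lasso solution of
#   (1/2n) ||y - b0 - X beta||^2 + lam * sum_j w_j |beta_j|
# by exhaustive enumeration of sign patterns (active-set KKT systems).
# Feasible only for small p; returns the unique minimizer.
oracle_weighted_lasso <- function(X, y, lam, w, tol = 1e-9) {
  n <- nrow(X)
  p <- ncol(X)
  xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  best <- NULL
  best_obj <- Inf
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (s in seq_len(nrow(signs))) {
    sg <- signs[s, ]
    A <- which(sg != 0)
    beta <- numeric(p)
    if (length(A)) {
      XA <- xc[, A, drop = FALSE]
      rhs <- crossprod(XA, yc) - n * lam * w[A] * sg[A]
      sol <- tryCatch(solve(crossprod(XA), rhs), error = function(e) NULL)
      if (is.null(sol)) next
      if (any(sign(sol) * sg[A] < 0)) next  # sign pattern inconsistent
      beta[A] <- sol
    }
    grad <- crossprod(xc, yc - xc %*% beta) / n
    inact <- setdiff(seq_len(p), A)
    if (length(inact) && any(abs(grad[inact]) > lam * w[inact] + tol)) next
    obj <- sum((yc - xc %*% beta)^2) / (2 * n) + lam * sum(w * abs(beta))
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- beta
    }
  }
  list(beta = best, intercept = mean(y) - sum(colMeans(X) * best),
       objective = best_obj)
}

# Brute-force AUC over all positive-negative pairs (ties count 1/2).
oracle_auc <- function(truth, score) {
  pos <- score[truth == 1]
  neg <- score[truth == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Standardized random Gaussian design (population-sd scaling, so columns
# satisfy sum(x^2) = n exactly).
make_std_design <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  standardize_columns(X)$x
}

# log-spaced decreasing grid from lmax down two decades
lambda_grid_for_test <- function(lmax, n) {
  exp(seq(log(lmax), log(lmax * 1e-2), length.out = n))
}
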