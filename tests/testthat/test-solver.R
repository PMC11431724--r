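test_that("soft_threshold matches its closed form", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_equal(soft_threshold(c(2, -2, 0.1), 0.5), c(1.5, -1.5, 0))
})

test_that("lambda_max has the stated closed form and null-fit property", {
  # single standardized column with x'y/n = 2 and weight 2
  x1 <- cbind(a = c(1, -1))
  y1 <- c(2, -2)
  expect_equal(compute_lambda_max(x1, y1, c(a = 2)), 1)

  # two columns, |x'y/n| = (1.5, 0.6), weights (1, 3): max(1.5, 0.2)
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  y <- 1.5 * X[, 1] + 0.6 * X[, 2]
  expect_equal(compute_lambda_max(X, y, c(a = 1, b = 3)), 1.5)

  # property: all-null at lambda_max, at least one active just below it
  set.seed(31)
  for (rep in 1:5) {
    Xr <- make_std_design(30, 4)
    yr <- rnorm(30) + Xr[, 1]
    w <- runif(4, 0.5, 2)
    names(w) <- colnames(Xr)
    lmax <- compute_lambda_max(Xr, yr, w)
    f <- fit_path(Xr, yr, w, lambda = c(lmax, 0.99 * lmax))
    expect_equal(unname(f$beta[, 1]), rep(0, 4))
    expect_gte(sum(f$beta[, 2] != 0), 1)
  }
  expect_error(compute_lambda_max(X, y, c(a = 0, b = 0)), "nothing to penalize")
})

test_that("orthonormal designs give the soft-thresholding solution", {
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))  # X'X = nI
  y <- 1.5 * X[, 1] + 0.3 * X[, 2]
  f <- fit_path(X, y, c(a = 1, b = 1), lambda = c(2, 0.5))
  expect_equal(unname(f$beta["a", 2]), 1.0, tolerance = 1e-7)
  expect_equal(unname(f$beta["b", 2]), 0)
})

test_that("the unpenalized limit reproduces least squares", {
  set.seed(32)
  X <- make_std_design(40, 5)
  y <- drop(X %*% c(1, -2, 0, 0.5, 0)) + rnorm(40)
  f <- fit_path(X, y, rep(1, 5), lambda = c(1, 0.1, 0))
  ols <- lm(y ~ X)
  expect_equal(unname(f$beta[, 3]), unname(coef(ols)[-1]), tolerance = 1e-6)
  expect_equal(f$intercept[3], unname(coef(ols)[1]), tolerance = 1e-6)
})

test_that("path solutions agree with the sign-enumeration QP oracle", {
  set.seed(33)
  for (rep in 1:5) {
    X <- make_std_design(20, 5)
    y <- drop(X %*% rnorm(5)) + rnorm(20)
    w <- runif(5, 0.5, 2)
    lmax <- compute_lambda_max(X, y, w)
    lams <- lmax * c(0.5, 0.2, 0.05)
    f <- fit_path(X, y, w, lambda = lams)
    for (l in 1:3) {
      o <- oracle_weighted_lasso(X, y, lams[l], w)
      expect_equal(unname(f$beta[, l]), o$beta, tolerance = 1e-6)
    }
  }
})

test_that("KKT residuals certify optimality and detect corruption", {
  set.seed(34)
  X <- make_std_design(50, 8)
  y <- drop(X %*% c(2, -1, rep(0, 6))) + rnorm(50)
  w <- rep(1.5, 8)
  f <- fit_path(X, y, w, nlambda = 30)
  kk <- kkt_residuals(f, X, y)
  expect_lt(max(kk[f$converged]), 1e-6)
  # null fit at lambda_max satisfies KKT by construction
  expect_lte(kk[1], 1e-8)
  # perturbing one coefficient produces a visible violation
  fbad <- f
  fbad$beta[1, 15] <- fbad$beta[1, 15] + 0.1
  expect_gt(kkt_residuals(fbad, X, y)[15], 1e-3)
})

test_that("weighted fit equals rescaled plain lasso (exact reparameterization)", {
  set.seed(35)
  for (rep in 1:3) {
    X <- make_std_design(40, 6)
    y <- drop(X %*% rnorm(6)) + rnorm(40)
    w <- runif(6, 0.3, 3)
    lmax <- compute_lambda_max(X, y, w)
    lams <- lambda_grid_for_test(lmax, 20)
    fw <- fit_path(X, y, w, lambda = lams, tol = 1e-12)
    Xs <- sweep(X, 2, w, `/`)
    fp <- fit_path(Xs, y, rep(1, 6), lambda = lams, tol = 1e-12)
    expect_equal(unname(fw$beta), unname(fp$beta / w), tolerance = 1e-8)
  }
})

test_that("gamma = 0 reproduces the glmnet lasso path", {
  skip_if_not_installed("glmnet")
  set.seed(36)
  X <- make_std_design(60, 8)
  y <- drop(X %*% c(1, -1, 0.5, rep(0, 5))) + rnorm(60)
  w <- rep(1, 8)
  f <- fit_path(X, y, w, nlambda = 40, tol = 1e-12)
  g <- glmnet::glmnet(X, y, lambda = f$lambda, standardize = FALSE,
                      thresh = 1e-14)
  expect_equal(unname(f$beta), unname(as.matrix(g$beta)), tolerance = 1e-6)

  # binomial family against glmnet's logistic lasso
  yb <- rbinom(60, 1, plogis(drop(X %*% c(1.5, -1, rep(0, 6)))))
  fb <- fit_path(X, yb, w, family = "binomial", nlambda = 25,
                 lambda_min_ratio = 0.05, tol = 1e-10)
  gb <- glmnet::glmnet(X, yb, family = "binomial", lambda = fb$lambda,
                       standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(fb$beta), unname(as.matrix(gb$beta)), tolerance = 1e-4)
  expect_equal(fb$intercept, unname(gb$a0), tolerance = 1e-4)
})

test_that("path predictions behave at the limits", {
  set.seed(37)
  X <- make_std_design(30, 4)
  y <- rbinom(30, 1, 0.5)
  f <- fit_path(X, y, rep(1, 4), family = "binomial", nlambda = 10)
  p <- predict(f, X, lambda_index = 1)
  expect_true(all(p > 0 & p < 1))
  expect_equal(unname(p), rep(mean(y), 30), tolerance = 1e-6)  # null model
  expect_error(fit_path(X, c(y[-1], 2), rep(1, 4), family = "binomial"),
               "0/1")
  Xbad <- X; Xbad[1, 1] <- Inf
  expect_error(fit_path(Xbad, y, rep(1, 4)), "non-finite")
})
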