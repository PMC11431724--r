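test_that("expand_terms produces the expected counts and canonical order", {
  covs3 <- lapply(paste0("x", 1:3), covariate, kind = "continuous")
  ts <- expand_terms(covs3, k = 1, poly = 2)
  expect_equal(nrow(ts$terms), 9)  # 3 mains + C(3,2) interactions + 3 polys
  expect_equal(unname(ts$group_sizes[c("main", "interaction1", "poly2")]),
               c(3L, 3L, 3L))
  expect_equal(ts$terms$id,
               c("x1", "x2", "x3", "x1:x2", "x1:x3", "x2:x3",
                 "x1^2", "x2^2", "x3^2"))

  ts1 <- expand_terms(list(covariate("x", "continuous")), k = 1, poly = 2)
  expect_equal(ts1$terms$id, c("x", "x^2"))  # no pairs exist

  # binary + continuous with seventh-order polynomials
  ts7 <- expand_terms(list(covariate("Official", "binary"),
                           covariate("Round", "continuous")),
                      k = 1, poly = 7)
  expect_equal(nrow(ts7$terms), 9)  # 2 mains + 1 interaction + 6 polys
  expect_equal(sum(ts7$terms$kind == "polynomial"), 6)
  expect_equal(ts7$terms$order[ts7$terms$kind == "polynomial"], 2:7)
  expect_true(all(ts7$terms$parents[ts7$terms$kind == "polynomial"] == "Round"))
})

test_that("interaction ids are order-invariant and expansion is deterministic", {
  covs <- lapply(c("b", "a", "c"), covariate, kind = "continuous")
  ts <- expand_terms(covs, k = 1, poly = 2)
  ts_rev <- expand_terms(rev(covs), k = 1, poly = 2)
  expect_identical(ts$terms$id, ts_rev$terms$id)
  expect_true("a:b" %in% ts$terms$id)
  expect_false("b:a" %in% ts$terms$id)
})

test_that("interaction counts match exhaustive enumeration for p <= 8", {
  for (p in 2:8) {
    covs <- lapply(paste0("x", 1:p), covariate, kind = "continuous")
    ts <- expand_terms(covs, k = 1, poly = 2)
    expect_equal(sum(ts$terms$kind == "interaction"), choose(p, 2))
  }
})

test_that("same-source dummies are never multiplied; binary gets no polys", {
  covs <- list(covariate("f_a", "binary", source = "f"),
               covariate("f_b", "binary", source = "f"),
               covariate("x", "continuous"))
  ts <- expand_terms(covs, k = 1, poly = 2)
  ids <- ts$terms$id[ts$terms$kind == "interaction"]
  expect_setequal(ids, c("f_a:x", "f_b:x"))  # no f_a:f_b
  expect_equal(ts$terms$id[ts$terms$kind == "polynomial"], "x^2")
})

test_that("expand_terms edge cases and errors", {
  expect_error(expand_terms(list(covariate("x", "continuous"),
                                 covariate("x", "continuous"))),
               "duplicate")
  # k + 1 exceeds covariate count: interactions empty, not an error
  ts <- expand_terms(list(covariate("x", "continuous")), k = 3, poly = 1)
  expect_equal(ts$terms$id, "x")
})

test_that("build_design_matrix computes products and powers elementwise", {
  d <- data.frame(x1 = c(1, 2), x2 = c(3, 4))
  ts <- expand_terms(d, k = 1, poly = 2)
  X <- build_design_matrix(d, ts)
  expect_equal(unname(X[, "x1:x2"]), c(3, 8))
  d2 <- data.frame(x = c(2, -1))
  X2 <- build_design_matrix(
    d2, expand_terms(list(covariate("x", "continuous")), k = 1, poly = 2))
  expect_equal(unname(X2[, "x^2"]), c(4, 1))
  # empty term set: 0 columns, n rows
  empty <- expand_terms(d, k = 1, poly = 2)
  empty$terms <- empty$terms[0, ]
  X0 <- build_design_matrix(d, empty)
  expect_equal(dim(X0), c(2L, 0L))
  # missing values are a hard error
  d3 <- data.frame(x1 = c(1, NA), x2 = c(3, 4))
  expect_error(build_design_matrix(d3, ts), "missing values")
})

test_that("penalty weights follow the group-size calibration", {
  covs <- lapply(paste0("x", 1:10), covariate, kind = "continuous")
  ts <- expand_terms(covs, k = 1, poly = 1)
  w <- assign_penalty_weights(ts, gamma = 0.5)
  expect_equal(unname(w$weights["x1"]), sqrt(10))
  expect_equal(unname(w$weights["x1:x2"]), sqrt(45))
  # interactions are penalized harder than mains whenever |B| > |A|
  expect_gt(w$weights[["x1:x2"]], w$weights[["x1"]])

  # gamma = 0: all weights 1 (plain lasso)
  w0 <- assign_penalty_weights(ts, gamma = 0)
  expect_true(all(w0$weights == 1))

  # polynomial weights use the cumulative dimension through order m
  covs4 <- lapply(paste0("x", 1:4), covariate, kind = "continuous")
  ts4 <- expand_terms(covs4, k = 1, poly = 2)
  w4 <- assign_penalty_weights(ts4, gamma = 0.5)
  expect_equal(unname(w4$weights["x1^2"]), sqrt(4 + 4))
  ts43 <- expand_terms(covs4, k = 1, poly = 3)
  w43 <- assign_penalty_weights(ts43, gamma = 0.5)
  expect_equal(unname(w43$weights["x1^3"]), sqrt(4 + 4 + 4))

  # all terms of one group share one weight
  expect_length(unique(w$weights[ts$terms$kind == "interaction"]), 1)
})
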