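test_that("collapse_rare_levels pools levels under the 10% rule", {
  x <- rep(c("A", "B", "C", "D", "E"), c(50, 30, 12, 5, 3))
  out <- collapse_rare_levels(x, 0.10)
  expect_setequal(unique(out$values), c("A", "B", "C", "other"))
  expect_equal(unname(out$merge_map[c("D", "E")]), c("other", "other"))

  x2 <- rep(c("A", "B"), c(60, 40))
  expect_equal(collapse_rare_levels(x2, 0.10)$values, x2)

  x3 <- rep(c("A", "B", "C"), c(92, 5, 3))
  expect_setequal(unique(collapse_rare_levels(x3, 0.10)$values),
                  c("A", "other"))

  # a literal "other" level forces the merged label to "other_merged"
  x4 <- rep(c("A", "other", "Z"), c(80, 15, 5))
  out4 <- collapse_rare_levels(x4, 0.10)
  expect_equal(unname(out4$merge_map["Z"]), "other_merged")
  expect_equal(unname(out4$merge_map["other"]), "other")
})

test_that("encode_categoricals uses reference coding against the mode", {
  d <- data.frame(f = rep(c("A", "B", "C"), c(5, 3, 2)), x = 1:10,
                  stringsAsFactors = FALSE)
  enc <- encode_categoricals(d)
  expect_setequal(names(enc$data), c("f_B", "f_C", "x"))  # A is reference
  expect_equal(sum(enc$data$f_B), 3)
  expect_equal(unname(enc$source_map["f_B"]), "f")

  db <- data.frame(g = rep(c("y", "n"), c(6, 4)), stringsAsFactors = FALSE)
  expect_equal(ncol(encode_categoricals(db)$data), 1)

  d1 <- data.frame(h = rep("only", 5), x = 1:5, stringsAsFactors = FALSE)
  expect_warning(enc1 <- encode_categoricals(d1), "single-level")
  expect_equal(names(enc1$data), "x")

  # applying a stored encoding reproduces the same columns on new data
  new <- data.frame(f = c("C", "A", "B"), x = 1:3, stringsAsFactors = FALSE)
  enc2 <- encode_categoricals(new, encoding = enc$encoding)
  expect_equal(enc2$data$f_C, c(1, 0, 0))
})

test_that("variance filter separates zv from nzv", {
  n <- 100
  cols <- cbind(const = rep(1, n),
                rare = rep(c(0, 1), c(96, 4)),   # ratio 24 > 19, unique% 2
                common = rep(c(0, 1), c(60, 40)),
                cont = seq_len(n))
  nzv <- variance_filter(cols, "nzv")
  zv <- variance_filter(cols, "zv")
  none <- variance_filter(cols, "none")
  expect_setequal(nzv$drop, c("const", "rare"))
  expect_equal(zv$drop, "const")
  expect_equal(none$drop, character(0))
  expect_equal(unname(nzv$reasons["rare"]), "near_zero_variance")
  expect_equal(unname(nzv$reasons["const"]), "zero_variance")
})

test_that("zv-dropped columns are a subset of nzv-dropped columns", {
  set.seed(11)
  for (rep in 1:5) {
    X <- cbind(matrix(rnorm(200), 50),
               rbinom(50, 1, 0.03), rep(2, 50), rbinom(50, 1, 0.4))
    colnames(X) <- paste0("c", 1:ncol(X))
    expect_true(all(variance_filter(X, "zv")$drop %in%
                      variance_filter(X, "nzv")$drop))
  }
})

test_that("standardization is exact, invertible, and replayable", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 0, 5))
  s <- standardize_columns(x)
  expect_equal(unname(colMeans(s$x)), c(0, 0))
  expect_equal(unname(colSums(s$x^2)), c(3, 3))  # population scaling
  back <- sweep(sweep(s$x, 2, s$scale, `*`), 2, s$center, `+`)
  expect_equal(unname(back), unname(x), tolerance = 1e-12)
  # replay on the same data reproduces the training matrix
  s2 <- standardize_columns(x, center = s$center, scale = s$scale)
  expect_identical(s2$x, s$x)
  # constant column: centered and flagged
  xc <- cbind(k = rep(7, 4))
  sc <- standardize_columns(xc)
  expect_true(sc$zero_scale)
  expect_equal(unname(sc$x[, 1]), rep(0, 4))
})

test_that("recipes fit on train never touch test data", {
  set.seed(21)
  d <- data.frame(x1 = rnorm(60), x2 = rnorm(60),
                  f = sample(c("a", "b", "c"), 60, TRUE, c(.5, .4, .1)),
                  y = rnorm(60))
  prep <- srl_prep(d, "y", k = 1, poly = 2, filter = "zv")
  test <- data.frame(x1 = rnorm(20), x2 = rnorm(20),
                     f = sample(c("a", "b"), 20, TRUE), y = rnorm(20))
  b1 <- bake_design(prep, test)
  test2 <- test
  test2$x1[1] <- test2$x1[1] + 100  # perturb one test row
  b2 <- bake_design(prep, test2)
  expect_equal(b1[-1, ], b2[-1, ])  # only that row's output changes
  # baking the training data reproduces the stored design exactly
  expect_equal(bake_design(prep, d), prep$x, tolerance = 1e-12)
})

test_that("srl_prep validates inputs", {
  d <- data.frame(x = rnorm(10), y = rnorm(10))
  expect_error(srl_prep(d, "z"), "not found")
  expect_error(srl_prep(data.frame(x = rnorm(10), y = rep(1, 10)), "y"),
               "constant")
  d$x[3] <- NA
  expect_error(srl_prep(d, "y"), "missing values")
})
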