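test_that("dataset filtering applies every inclusion rule", {
  meta <- data.frame(
    name = c("a", "b", "c", "d", "e", "fri_sim1"),
    endpoint = c("binary", "continuous", "binary", "categorical",
                 "continuous", "continuous"),
    n_obs = c(12000, 500, 5000, 800, 900, 400),
    n_features = c(10, 60, 30, 5, 20, 10))
  kept <- filter_datasets(meta)
  expect_equal(kept$name, "e")  # 12000 obs / 60 features / 150k cells /
                                # categorical endpoint / friedman all excluded
  expect_equal(kept$n_cells, 900 * 20)
})

test_that("bakeoff arms share splits and reruns are bit-identical", {
  suite <- gen_benchmark_suite(n_datasets = 3, n = 150, seed = 10)
  r1 <- suppressWarnings(run_bakeoff(suite, seed = 4, srl_args = list(nlambda = 40)))
  r2 <- suppressWarnings(run_bakeoff(suite, seed = 4, srl_args = list(nlambda = 40)))
  expect_identical(r1$test_metric, r2$test_metric)
  expect_equal(nrow(r1), 6)  # 3 datasets x 2 arms
  expect_true(all(tapply(r1$seed, r1$dataset, function(s) length(unique(s))) == 1))
})

test_that("the SRL arm under the null configuration equals the lasso arm", {
  suite <- gen_benchmark_suite(n_datasets = 3, n = 150, seed = 11)
  res <- suppressWarnings(
    run_bakeoff(suite, seed = 2,
                srl_args = list(gamma = 0, k = 0, poly = 1, nlambda = 40)))
  wide <- split(res$test_metric, res$algorithm)
  expect_equal(wide$srl, wide$lasso)
})

test_that("within_pct_of_best implements the 5% rule with ties", {
  res <- data.frame(dataset = rep(c("d1", "d2", "d3"), each = 2),
                    algorithm = rep(c("rf", "srl"), 3),
                    test_metric = c(0.90, 0.87, 0.80, 0.80, 0.70, 0.60))
  s <- within_pct_of_best(res)
  srl <- s[s$algorithm == "srl", ]
  rf <- s[s$algorithm == "rf", ]
  # d1: srl within 5% (0.87 >= 0.855) but not best; d2 tie: both best
  expect_equal(srl$best_pct, 100 / 3)
  expect_equal(rf$best_pct, 100)
  expect_equal(srl$within_pct, 200 / 3)

  all_equal <- data.frame(dataset = rep(c("d1", "d2"), each = 2),
                          algorithm = rep(c("a", "b"), 2),
                          test_metric = rep(0.5, 4))
  expect_true(all(within_pct_of_best(all_equal)$best_pct == 100))
})

test_that("meta_analyze handles the degenerate equal-performance case", {
  res <- data.frame(dataset = rep(paste0("d", 1:4), each = 3),
                    algorithm = rep(c("srl", "lasso", "rf"), 4),
                    test_metric = 0.7)
  mm <- suppressWarnings(meta_analyze(res))
  expect_equal(mm$estimate[mm$term == "(Intercept)"], 0.7, tolerance = 1e-8)
  expect_equal(mm$estimate[mm$term != "(Intercept)"], c(0, 0),
               tolerance = 1e-8)
})

test_that("a singular random intercept falls back to fixed dataset effects", {
  set.seed(73)
  # no dataset-level heterogeneity at all: variance component collapses
  res <- expand.grid(dataset = paste0("d", 1:10),
                     algorithm = c("srl", "lasso"),
                     stringsAsFactors = FALSE)
  res$test_metric <- ifelse(res$algorithm == "srl", 0.7, 0.65) +
    rnorm(nrow(res), sd = 0.05)
  mm <- withCallingHandlers(
    meta_analyze(res),
    warning = function(w) {
      expect_match(conditionMessage(w), "singular|converge", ignore.case = TRUE)
      invokeRestart("muffleWarning")
    })
  expect_equal(mm$estimate[mm$term == "lasso"], -0.05, tolerance = 0.05)
})

test_that("re-referencing shifts estimates by the reference contrast", {
  set.seed(71)
  ds <- paste0("d", 1:12)
  eff <- rnorm(12, 0.6, 0.1)
  res <- expand.grid(dataset = ds, algorithm = c("srl", "lasso", "rf"),
                     stringsAsFactors = FALSE)
  offs <- c(srl = 0, lasso = -0.05, rf = -0.12)
  res$test_metric <- eff[match(res$dataset, ds)] +
    offs[res$algorithm] + rnorm(nrow(res), sd = 0.02)
  m_srl <- meta_analyze(res, reference = "srl")
  m_lasso <- meta_analyze(res, reference = "lasso")
  est <- function(m, term) m$estimate[m$term == term]
  expect_equal(est(m_lasso, "rf"), est(m_srl, "rf") - est(m_srl, "lasso"),
               tolerance = 1e-6)
  expect_equal(est(m_lasso, "srl"), -est(m_srl, "lasso"), tolerance = 1e-6)
  expect_gt(attr(m_srl, "ranef_var"), 0)
})

test_that("meta_analyze recovers planted offsets on one synthetic table", {
  set.seed(72)
  ds <- paste0("d", 1:40)
  eff <- rnorm(40, 0.6, 0.15)
  res <- expand.grid(dataset = ds, algorithm = c("srl", "lasso", "rf"),
                     stringsAsFactors = FALSE)
  offs <- c(srl = 0, lasso = -0.05, rf = -0.15)
  res$test_metric <- eff[match(res$dataset, ds)] +
    offs[res$algorithm] + rnorm(nrow(res), sd = 0.02)
  mm <- meta_analyze(res)
  expect_equal(mm$estimate[mm$term == "lasso"], -0.05, tolerance = 0.02)
  expect_equal(mm$estimate[mm$term == "rf"], -0.15, tolerance = 0.02)
  expect_lt(mm$p_value[mm$term == "rf"], 0.001)
})

test_that("pmlb reader round-trips a gzipped tab-separated file", {
  d <- data.frame(a = 1:5, b = c(0.5, 1, 1.5, 2, 2.5), target = c(0, 1, 0, 1, 0))
  tmp <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(tmp, "w")
  write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  rd <- read_pmlb(tmp)
  expect_equal(rd, d)
  tmp2 <- tempfile(fileext = ".tsv")
  write.table(d[, 1:2], tmp2, sep = "\t", row.names = FALSE)
  expect_error(read_pmlb(tmp2), "target")
  unlink(c(tmp, tmp2))
})
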