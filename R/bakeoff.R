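#' Filter benchmark datasets by the study's inclusion rules
#'
#' Keeps datasets with a binary or continuous endpoint, fewer than 10,000
#' observations, 50 or fewer predictors, fewer than 100,000 total predictor
#' cells (observations x predictors), and not generated by the Friedman
#' simulation family.
#'
#' @param metadata Data frame with columns `name`, `endpoint` (one of
#'   `"binary"`, `"continuous"`, `"categorical"`), `n_obs`, `n_features`,
#'   and optionally `friedman` (logical; defaults to a name-based rule:
#'   any name containing `"fri_"` or starting with `"friedman"`).
#' @param max_obs,max_features,max_cells Inclusion thresholds.
#' @return The included subset of `metadata`, with an `n_cells` column.
#' @export
filter_datasets <- function(metadata, max_obs = 10000, max_features = 50,
                            max_cells = 100000) {
  stopifnot(all(c("name", "endpoint", "n_obs", "n_features") %in%
                  names(metadata)))
  metadata$n_cells <- metadata$n_obs * metadata$n_features
  if (is.null(metadata$friedman))
    metadata$friedman <- grepl("(^|_)fri_|^friedman", metadata$name)
  keep <- metadata$endpoint %in% c("binary", "continuous") &
    metadata$n_obs < max_obs &
    metadata$n_features <= max_features &
    metadata$n_cells < max_cells &
    !metadata$friedman
  metadata[keep, , drop = FALSE]
}

# built-in arms; extra arms are user functions
# f(train, test, target, family, seed) -> list(cv_metric, test_metric, pred)
builtin_arm <- function(name, srl_args = list()) {
  force(name); force(srl_args)
  function(train, test, target, family, seed) {
    args <- c(list(data = train, target = target, family = family,
                   seed = seed), srl_args)
    if (name == "lasso") {
      args$gamma <- 0; args$k <- 0; args$poly <- 1
    }
    model <- do.call(srl_fit, args)
    truth <- test[[target]]
    if (!is.null(model$prep$y_levels))
      truth <- as.numeric(factor(as.character(truth),
                                 levels = model$prep$y_levels)) - 1
    pred <- predict(model, test, lambda = "lambda_min")
    if (family == "binomial") {
      list(cv_metric = NA_real_,
           test_metric = auc(as.numeric(truth), pred))
    } else {
      list(cv_metric = model$cv$cv_r2[model$cv$lambda_min],
           test_metric = r_squared(as.numeric(truth), pred))
    }
  }
}

#' Run an out-of-the-box benchmarking comparison
#'
#' For each dataset: one 80/20 train-test split, shared across every
#' algorithm; each arm is tuned by its own default 10-fold CV on the
#' training set and evaluated on the test set.  The built-in arms are
#' `"srl"` (defaults: k = 1, poly = 2, nzv filter, gamma = 0.5) and
#' `"lasso"` (gamma = 0, k = 0, poly = 1, i.e. a plain lasso on main
#' effects).  Black-box arms can be supplied as functions through
#' `extra_arms`.  The test metric is AUC for binary endpoints and (raw)
#' test R-squared for continuous ones; an arm failing on a dataset is
#' recorded as `NA` and the run continues.
#'
#' @param datasets Named list; each element a data frame with a `target`
#'   column, or a list with `data` and `target`.
#' @param arms Character vector of built-in arm names (subset of
#'   `c("srl", "lasso")`).
#' @param seed Integer seed; dataset i uses `seed + i` for its split and CV.
#' @param test_fraction Held-out proportion (default 0.20).
#' @param srl_args Extra arguments for the `"srl"` arm (e.g.
#'   `list(gamma = 0, k = 0, poly = 1)` to force the lasso configuration).
#' @param extra_arms Named list of arm functions
#'   `f(train, test, target, family, seed)` returning
#'   `list(cv_metric, test_metric)`.
#' @return Data frame of class `"bakeoff_result"`: one row per dataset x
#'   algorithm with `dataset`, `algorithm`, `endpoint`, `cv_metric`,
#'   `test_metric` (higher is better; R-squared is reported raw, clamp
#'   before summarizing), `runtime`, `seed`.
#' @export
run_bakeoff <- function(datasets, arms = c("srl", "lasso"), seed = 1,
                        test_fraction = 0.20, srl_args = list(),
                        extra_arms = list()) {
  stopifnot(all(arms %in% c("srl", "lasso")))
  # srl_args (minus the identity-defining gamma/k/poly, which the lasso arm
  # overrides) apply to both built-in arms so they stay comparable
  arm_funs <- c(setNames(lapply(arms, builtin_arm, srl_args = srl_args), arms),
                extra_arms)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  rows <- list()
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    if (is.data.frame(d)) d <- list(data = d, target = "target")
    df <- d$data
    target <- d$target
    y <- df[[target]]
    binary <- length(unique(y)) == 2
    family <- if (binary) "binomial" else "gaussian"
    ds_seed <- seed + i
    split <- train_test_split(nrow(df), test_fraction, seed = ds_seed,
                              labels = if (binary) y else NULL)
    train <- df[split$train, , drop = FALSE]
    test <- df[split$test, , drop = FALSE]
    for (arm in names(arm_funs)) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch(arm_funs[[arm]](train, test, target, family, ds_seed),
                      error = function(e) {
                        warning("arm '", arm, "' failed on '",
                                names(datasets)[i], "': ",
                                conditionMessage(e))
                        list(cv_metric = NA_real_, test_metric = NA_real_)
                      })
      rows[[length(rows) + 1]] <- data.frame(
        dataset = names(datasets)[i], algorithm = arm,
        endpoint = if (binary) "binary" else "continuous",
        cv_metric = res$cv_metric, test_metric = res$test_metric,
        runtime = proc.time()[["elapsed"]] - t0, seed = ds_seed,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bakeoff_result", "data.frame")
  out
}

#' Best and within-5%-of-best summary
#'
#' Per dataset, the best algorithm attains the maximum test metric (higher
#' is better: AUC, or clamped test R-squared); an algorithm is "within
#' tolerance" when its metric is at least `(1 - tolerance)` times the best.
#' Ties credit all tied algorithms.
#'
#' @param results A [run_bakeoff()] result (or any data frame with
#'   `dataset`, `algorithm` and a metric column).
#' @param metric Metric column name (default `"test_metric"`); R-squared
#'   values are clamped at zero before comparison.
#' @param tolerance Relative tolerance (default 0.05).
#' @return Data frame with one row per algorithm: `best_pct` and
#'   `within_pct` (percentages over the datasets where the algorithm ran).
#' @export
within_pct_of_best <- function(results, metric = "test_metric",
                               tolerance = 0.05) {
  m <- clamp_r_squared(results[[metric]])  # no-op for AUC (already >= 0)
  ds <- split(seq_len(nrow(results)), results$dataset)
  algs <- unique(results$algorithm)
  best <- within <- total <- setNames(numeric(length(algs)), algs)
  for (idx in ds) {
    v <- m[idx]
    if (all(is.na(v))) next
    top <- max(v, na.rm = TRUE)
    for (ii in idx) {
      a <- results$algorithm[ii]
      if (is.na(m[ii])) next
      total[a] <- total[a] + 1
      if (m[ii] == top) best[a] <- best[a] + 1
      if (m[ii] >= (1 - tolerance) * top) within[a] <- within[a] + 1
    }
  }
  data.frame(algorithm = algs,
             n_datasets = as.integer(total[algs]),
             best_pct = 100 * best[algs] / pmax(total[algs], 1),
             within_pct = 100 * within[algs] / pmax(total[algs], 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Random-intercept meta-analysis of benchmark results
#'
#' Fits `metric ~ algorithm + (1 | dataset)`: fixed effects for the
#' algorithms with the SRL as the reference, and a random intercept per
#' dataset absorbing dataset-specific signal-to-noise differences.  The
#' intercept is the expected metric for the reference algorithm; each
#' algorithm estimate is its expected change relative to the reference.
#' Confidence intervals and p-values use the normal approximation to the
#' Wald statistic.  If the random-intercept variance is estimated as
#' singular, the model falls back to fixed dataset effects with a warning.
#'
#' @param results A [run_bakeoff()] result or any data frame with
#'   `dataset`, `algorithm` and the metric column.
#' @param metric Metric column (default `"test_metric"`); R-squared values
#'   should already be clamped ([clamp_r_squared()]) by the caller when
#'   mixing with AUC conventions.
#' @param reference Reference algorithm (default `"srl"`).
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame of class `"meta_model_result"`: one row per term
#'   (`(Intercept)` plus each non-reference algorithm) with `estimate`,
#'   `se`, `conf_low`, `conf_high`, `p_value`; attributes `ranef_var`
#'   (dataset random-intercept variance) and `singular`.
#' @export
meta_analyze <- function(results, metric = "test_metric", reference = "srl",
                         conf_level = 0.95) {
  d <- data.frame(dataset = factor(results$dataset),
                  algorithm = results$algorithm,
                  y = results[[metric]])
  d <- d[!is.na(d$y), , drop = FALSE]
  if (length(unique(d$algorithm)) < 2) stop("need at least 2 algorithms")
  if (length(unique(d$dataset)) < 3) stop("need at least 3 datasets")
  if (!reference %in% d$algorithm) stop("reference algorithm '", reference,
                                        "' absent from results")
  d$algorithm <- stats::relevel(factor(d$algorithm), ref = reference)
  fit <- suppressMessages(lme4::lmer(y ~ algorithm + (1 | dataset), data = d,
                                     REML = TRUE))
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("random-intercept variance is singular; ",
            "falling back to fixed dataset effects")
    lf <- stats::lm(y ~ algorithm + dataset, data = d)
    cf <- summary(lf)$coefficients
    keep <- grep("^\\(Intercept\\)$|^algorithm", rownames(cf))
    est <- cf[keep, 1]; se <- cf[keep, 2]
    ranef_var <- NA_real_
  } else {
    cf <- summary(fit)$coefficients
    est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
    vc <- as.data.frame(lme4::VarCorr(fit))
    ranef_var <- vc$vcov[vc$grp == "dataset"]
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(
    term = sub("^algorithm", "", names(est)),
    estimate = unname(est), se = unname(se),
    conf_low = unname(est - z * se), conf_high = unname(est + z * se),
    p_value = unname(2 * pnorm(-abs(est / se))),
    stringsAsFactors = FALSE)
  attr(out, "ranef_var") <- ranef_var
  attr(out, "singular") <- singular
  attr(out, "reference") <- reference
  class(out) <- c("meta_model_result", "data.frame")
  out
}
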