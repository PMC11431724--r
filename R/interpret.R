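# Sparse polynomial algebra over the raw (pre-standardization) parent
# columns.  A polynomial is a list of monomials keyed by a canonical id;
# each monomial holds integer powers per parent and a coefficient.  Used to
# back-transform coefficients fitted on the standardized scale into an
# exactly prediction-equivalent original-scale representation.

mono_key <- function(powers) {
  powers <- powers[powers > 0]
  if (!length(powers)) return("(Intercept)")
  nms <- sort(names(powers))
  paste(ifelse(powers[nms] == 1, nms, paste0(nms, "^", powers[nms])),
        collapse = ":")
}

poly_new <- function(coef = numeric(0), powers = list()) {
  structure(list(coef = coef, powers = powers), class = "raw_poly")
}

poly_const <- function(c0) {
  poly_new(setNames(c0, "(Intercept)"),
           setNames(list(integer(0)), "(Intercept)"))
}

# a*x + b for one raw column
poly_linear <- function(name, a, b) {
  p <- poly_const(b)
  key <- mono_key(setNames(1L, name))
  p$coef[key] <- a
  p$powers[[key]] <- setNames(1L, name)
  p
}

poly_add <- function(p1, p2, scale2 = 1) {
  for (key in names(p2$coef)) {
    if (is.null(p1$powers[[key]])) p1$powers[[key]] <- p2$powers[[key]]
    p1$coef[key] <- (if (key %in% names(p1$coef)) p1$coef[key] else 0) +
      scale2 * p2$coef[key]
  }
  p1
}

poly_mul <- function(p1, p2) {
  out <- poly_new()
  for (k1 in names(p1$coef)) for (k2 in names(p2$coef)) {
    pw <- p1$powers[[k1]]
    for (nm in names(p2$powers[[k2]])) {
      pw[nm] <- (if (nm %in% names(pw)) pw[nm] else 0L) + p2$powers[[k2]][nm]
    }
    key <- mono_key(pw)
    if (is.null(out$powers[[key]])) out$powers[[key]] <- pw[pw > 0]
    out$coef[key] <- (if (key %in% names(out$coef)) out$coef[key] else 0) +
      p1$coef[k1] * p2$coef[k2]
  }
  out
}

poly_pow <- function(p, m) {
  out <- poly_const(1)
  for (i in seq_len(m)) out <- poly_mul(out, p)
  out
}

eval_raw_poly <- function(p, parents) {
  out <- numeric(nrow(parents))
  for (key in names(p$coef)) {
    pw <- p$powers[[key]]
    v <- rep(1, nrow(parents))
    for (nm in names(pw)) v <- v * parents[[nm]]^pw[nm]
    out <- out + p$coef[key] * v
  }
  out
}

# polynomial, in raw parent columns, equal to the model's linear predictor
# at the given path index
original_polynomial <- function(model, lambda = "lambda_min") {
  idx <- select_index(model, lambda)
  prep <- model$prep
  beta <- model$path$beta[, idx]
  a0 <- model$path$intercept[idx]
  out <- poly_const(a0)
  terms <- prep$termset$terms
  parent_poly <- function(nm) {
    m <- prep$parent_center[[nm]]; s <- prep$parent_scale[[nm]]
    poly_linear(nm, 1 / s, -m / s)
  }
  for (t in seq_len(nrow(terms))) {
    b <- beta[terms$id[t]]
    if (b == 0) next
    g <- switch(terms$kind[t],
      main = parent_poly(terms$parents[[t]]),
      interaction = Reduce(poly_mul, lapply(terms$parents[[t]], parent_poly)),
      polynomial = poly_pow(parent_poly(terms$parents[[t]]), terms$order[t]))
    M <- prep$design_center[[terms$id[t]]]
    S <- prep$design_scale[[terms$id[t]]]
    # standardized column is (g(x) - M) / S
    out <- poly_add(out, g, scale2 = b / S)
    out$coef["(Intercept)"] <- out$coef["(Intercept)"] - b * M / S
  }
  out
}

# predictor columns after collapsing + dummy encoding but before scaling
parent_frame <- function(prep, newdata) {
  preds <- newdata[prep$raw_predictors]
  for (nm in names(prep$merge_maps))
    preds[[nm]] <- collapse_rare_levels(preds[[nm]],
                                        merge_map = prep$merge_maps[[nm]])$values
  encode_categoricals(preds, encoding = prep$encoding)$data[prep$parent_names]
}

classify_monomial <- function(powers) {
  if (!length(powers)) return("intercept")
  if (length(powers) == 1 && powers == 1) return("main")
  if (all(powers == 1)) return("interaction")
  if (length(powers) == 1) return("polynomial")
  "mixed"
}

#' Original-scale coefficient table
#'
#' Back-transforms the standardized-scale coefficients of a fitted SRL
#' model to the scale of the raw (dummy-encoded) predictor columns, by
#' symbolically expanding each selected term through its standardization.
#' Interactions of centered parents spill lower-order contributions into
#' main effects and the intercept; those rows appear too, so evaluating the
#' original-scale coefficients on raw features reproduces the model's
#' linear predictor exactly.  Zero coefficients are reported as exactly 0.
#'
#' @param model An [srl_fit()] object.
#' @return A data frame of class `"coefficient_table"` with columns `term`,
#'   `kind`, `estimate_min`, `estimate_1se` (original scale), `std_min`,
#'   `std_1se` (standardized scale; `NA` for monomials that only arise from
#'   expansion), and `selected_at` (`"both"`, `"lambda_min"`,
#'   `"lambda_1se"`, or `"none"`).
#' @export
coefficient_table <- function(model) {
  pmin_ <- original_polynomial(model, "lambda_min")
  p1se <- original_polynomial(model, "lambda_1se")
  keys <- union(names(pmin_$coef), names(p1se$coef))
  terms <- model$prep$termset$terms
  keys <- union(keys, c("(Intercept)", terms$id))
  powers <- c(pmin_$powers, p1se$powers)
  bmin <- model$beta_min
  b1se <- model$beta_1se
  rows <- lapply(keys, function(key) {
    pw <- powers[[key]]
    kind <- if (key %in% terms$id) {
      terms$kind[match(key, terms$id)]
    } else if (key == "(Intercept)") "intercept"
    else if (!is.null(pw)) classify_monomial(pw)
    else "main"
    is_term <- key %in% names(bmin)
    sm <- if (is_term) unname(bmin[key]) else NA_real_
    s1 <- if (is_term) unname(b1se[key]) else NA_real_
    sel <- if (!is_term) NA_character_
      else if (sm != 0 && s1 != 0) "both"
      else if (sm != 0) "lambda_min"
      else if (s1 != 0) "lambda_1se"
      else "none"
    data.frame(term = key, kind = kind,
               estimate_min = if (key %in% names(pmin_$coef))
                 unname(pmin_$coef[key]) else 0,
               estimate_1se = if (key %in% names(p1se$coef))
                 unname(p1se$coef[key]) else 0,
               std_min = sm, std_1se = s1, selected_at = sel,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  kind_rank <- c(intercept = 0, main = 1, interaction = 2, polynomial = 3,
                 mixed = 4)
  out <- out[order(kind_rank[out$kind], out$term), ]
  rownames(out) <- NULL
  class(out) <- c("coefficient_table", "data.frame")
  out
}

#' Effect profile of one covariate
#'
#' Predicted outcome over a grid of values of a focal covariate, holding
#' every other covariate at its training median (numeric) or mode
#' (categorical).  With a moderator, one curve is produced per moderator
#' level (for a continuous moderator, its training quartiles), which
#' displays interaction effects; a quadratic term shows up as curvature.
#' Predictions are on the response scale (probabilities for binomial
#' models).
#'
#' @param model An [srl_fit()] object.
#' @param focal Name of the focal predictor.
#' @param moderator Optional second predictor.
#' @param grid_size Grid length for a continuous focal (default 100).
#' @param lambda Path selection (default `"lambda_1se"`, the compact model).
#' @return Data frame of class `"effect_profile"` with the focal value, the
#'   moderator level (if any) and the prediction.
#' @export
effect_profile <- function(model, focal, moderator = NULL, grid_size = 100,
                           lambda = "lambda_1se") {
  smry <- model$prep$train_summary
  if (!focal %in% names(smry)) stop("focal covariate '", focal,
                                    "' not in the training schema")
  if (!is.null(moderator) && !moderator %in% names(smry))
    stop("moderator '", moderator, "' not in the training schema")
  grid_of <- function(nm, k = grid_size) {
    s <- smry[[nm]]
    if (s$kind == "numeric") {
      if (k <= 4) quantile(s$range, probs = seq(0.25, 0.75, length.out = k),
                           names = FALSE)
      else seq(s$range[1], s$range[2], length.out = k)
    } else s$levels
  }
  ref_of <- function(nm) {
    s <- smry[[nm]]
    if (s$kind == "numeric") s$median else s$mode
  }
  focal_vals <- grid_of(focal)
  mod_vals <- if (is.null(moderator)) NA else {
    s <- smry[[moderator]]
    if (s$kind == "numeric") {
      # observed values for discrete moderators, else low/mid/high references
      s$values %||% unique(c(s$range[1], s$median, s$range[2]))
    } else s$levels
  }
  grid <- expand.grid(focal = focal_vals, moderator = mod_vals,
                      stringsAsFactors = FALSE)
  newdata <- as.data.frame(lapply(setNames(nm = names(smry)), function(nm)
    rep(ref_of(nm), nrow(grid))), optional = TRUE, check.names = FALSE)
  newdata[[focal]] <- grid$focal
  if (!is.null(moderator)) newdata[[moderator]] <- grid$moderator
  grid$prediction <- predict(model, newdata, lambda = lambda)
  if (is.null(moderator)) grid$moderator <- NULL
  names(grid)[1] <- focal
  if (!is.null(moderator)) names(grid)[2] <- moderator
  attr(grid, "focal") <- focal
  attr(grid, "moderator") <- moderator
  class(grid) <- c("effect_profile", "data.frame")
  grid
}

`%||%` <- function(a, b) if (is.null(a)) b else a
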