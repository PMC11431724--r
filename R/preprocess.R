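#' Collapse rare categorical levels
#'
#' Every level observed in less than `threshold` of the column is mapped to
#' a single pooled level, `"other"` (or `"other_merged"` if a level named
#' `"other"` already exists).  Levels at or above the threshold are kept.
#'
#' @param column A character or factor vector.
#' @param threshold Proportion below which a level is rare (default 0.10).
#' @param merge_map Optional previously fitted map (named character,
#'   level -> mapped level); when supplied it is applied as-is, with unseen
#'   levels mapped to the pooled level if one exists, else kept.
#' @return List with `values` (mapped character vector) and `merge_map`.
#' @export
collapse_rare_levels <- function(column, threshold = 0.10, merge_map = NULL) {
  x <- as.character(column)
  if (!length(x)) stop("empty column")
  if (is.null(merge_map)) {
    stopifnot(threshold >= 0, threshold < 0.5)
    freq <- table(x) / length(x)
    levs <- names(freq)
    rare <- levs[freq < threshold]
    other <- if ("other" %in% levs) "other_merged" else "other"
    merge_map <- setNames(levs, levs)
    if (length(rare)) merge_map[rare] <- other
  }
  pooled <- setdiff(unique(unname(merge_map)), names(merge_map))
  out <- merge_map[x]
  if (anyNA(out)) {  # unseen level at apply time
    fill <- if (length(pooled)) pooled[1] else x[is.na(out)]
    out[is.na(out)] <- fill
  }
  list(values = unname(out), merge_map = merge_map)
}

#' Dummy-encode categorical columns
#'
#' Each categorical column with `L` observed levels becomes `L - 1`
#' indicator columns against a reference level, the most frequent one.
#' Single-level columns (e.g. after rare-level collapsing) are dropped
#' with a warning.
#'
#' @param data A data frame; factor/character columns are encoded, numeric
#'   columns are passed through.
#' @param encoding Optional fitted encoding (from a previous call) to apply
#'   to new data: a list per categorical with `reference` and `levels`.
#' @return List with `data` (all-numeric data frame), `source_map` (named
#'   character, dummy column -> parent categorical) and `encoding`.
#' @export
encode_categoricals <- function(data, encoding = NULL) {
  out <- list()
  source_map <- character(0)
  enc <- if (is.null(encoding)) list() else encoding
  fitting <- is.null(encoding)
  for (nm in names(data)) {
    x <- data[[nm]]
    if (is.numeric(x) || is.logical(x)) {
      out[[nm]] <- as.numeric(x)
      next
    }
    x <- as.character(x)
    if (fitting) {
      tab <- sort(table(x), decreasing = TRUE)
      enc[[nm]] <- list(reference = names(tab)[1],
                        levels = setdiff(names(tab), names(tab)[1]))
    }
    e <- enc[[nm]]
    if (is.null(e) || !length(e$levels)) {
      if (fitting) warning("dropping single-level column '", nm, "'")
      next
    }
    for (lev in e$levels) {
      dn <- dummy_name(nm, lev)
      out[[dn]] <- as.numeric(x == lev)
      source_map[dn] <- nm
    }
  }
  list(data = as.data.frame(out, optional = TRUE, check.names = FALSE),
       source_map = source_map, encoding = enc)
}

dummy_name <- function(col, lev) {
  paste0(col, "_", gsub("[^0-9A-Za-z._]", ".", lev))
}

#' Variance-based column filter
#'
#' `mode = "zv"` drops exactly the constant columns.  `mode = "nzv"`
#' additionally drops near-zero-variance columns: those whose ratio of the
#' most frequent value's count to the second most frequent value's count
#' exceeds `freq_ratio` (default 95/5 = 19) *and* whose percentage of
#' distinct values is below `unique_pct` (default 10).  `mode = "none"`
#' drops nothing.
#'
#' @param x A numeric matrix or data frame of candidate columns.
#' @param mode One of `"nzv"`, `"zv"`, `"none"`.
#' @param freq_ratio,unique_pct Near-zero-variance thresholds.
#' @return List with `keep` and `drop` (column names) and `reasons` (named
#'   character for dropped columns: `"zero_variance"` or
#'   `"near_zero_variance"`).
#' @export
variance_filter <- function(x, mode = c("nzv", "zv", "none"),
                            freq_ratio = 95 / 5, unique_pct = 10) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("V", seq_len(ncol(x)))
  n <- nrow(x)
  reasons <- character(0)
  for (j in seq_len(ncol(x))) {
    if (mode == "none") break
    tab <- sort(tabulate(match(x[, j], unique(x[, j]))), decreasing = TRUE)
    if (length(tab) == 1) {
      reasons[nms[j]] <- "zero_variance"
    } else if (mode == "nzv") {
      fr <- tab[1] / tab[2]
      up <- 100 * length(tab) / n
      if (fr > freq_ratio && up < unique_pct)
        reasons[nms[j]] <- "near_zero_variance"
    }
  }
  drop <- as.character(names(reasons) %||% character(0))
  list(keep = setdiff(nms, drop), drop = drop, reasons = reasons)
}

#' Center and scale columns
#'
#' Standardizes to mean 0 and scale 1, using the population (divide-by-n)
#' standard deviation so that standardized columns satisfy `sum(x^2) = n`
#' exactly, which the path solver exploits.  Zero-scale columns are left
#' centered and flagged.  With `center`/`scale` supplied, applies the
#' stored training statistics (fit-on-train / apply-anywhere).
#'
#' @param x Numeric matrix.
#' @param center,scale Optional stored statistics.
#' @return List with `x`, `center`, `scale`, `zero_scale` (logical).
#' @export
standardize_columns <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) {
    center <- colMeans(x)
    s <- sqrt(colMeans(sweep(x, 2, center)^2))
    zero <- s < 1e-12
    scale <- ifelse(zero, 1, s)
  } else {
    zero <- scale == 1 & apply(x, 2, function(c) length(unique(c)) == 1)
  }
  xs <- sweep(sweep(x, 2, center), 2, scale, `/`)
  list(x = xs, center = center, scale = scale, zero_scale = unname(zero))
}

#' Fit the SRL preprocessing-and-expansion recipe
#'
#' Runs the full data-preparation pipeline on training data and freezes
#' every statistic so it can be replayed on new data: rare-level collapsing
#' on categoricals, dummy encoding against the most frequent level,
#' centering/scaling of the parent columns, term expansion via
#' [expand_terms()], construction of the candidate design from the
#' standardized parents, the variance filter (which runs *after* expansion,
#' so near-constant interaction columns are removed before the supervised
#' step), standardization of the retained columns, and penalty weights on
#' the retained candidate set.
#'
#' @param data Training data frame including the target column.
#' @param target Name of the target column.
#' @param k,poly,gamma See [expand_terms()] and [assign_penalty_weights()].
#' @param filter Variance-filter mode: `"nzv"` (default), `"zv"`, `"none"`.
#' @param rare_threshold Rare-level proportion (default 0.10).
#' @param freq_ratio,unique_pct Near-zero-variance thresholds.
#' @return An object of class `"srl_prep"` with the standardized design
#'   (`$x`), response (`$y`), weights, term metadata and all frozen
#'   statistics.  Apply to new data with [bake_design()].
#' @export
srl_prep <- function(data, target, k = 1, poly = 2,
                     filter = c("nzv", "zv", "none"),
                     rare_threshold = 0.10, gamma = 0.5,
                     freq_ratio = 95 / 5, unique_pct = 10) {
  filter <- match.arg(filter)
  if (!target %in% names(data)) stop("target column '", target, "' not found")
  y <- data[[target]]
  if (is.factor(y) || is.character(y)) {
    y <- as.factor(as.character(y))
    if (nlevels(y) != 2) stop("non-numeric target must have exactly 2 levels")
    y_levels <- levels(y)
    y <- as.numeric(y) - 1
  } else {
    y_levels <- NULL
    y <- as.numeric(y)
  }
  if (anyNA(y)) stop("missing values in target")
  if (length(unique(y)) < 2) stop("target is constant")
  preds <- data[setdiff(names(data), target)]

  # rare-level collapsing on categoricals
  merge_maps <- list()
  for (nm in names(preds)) {
    if (!is.numeric(preds[[nm]]) && !is.logical(preds[[nm]])) {
      cl <- collapse_rare_levels(preds[[nm]], rare_threshold)
      preds[[nm]] <- cl$values
      merge_maps[[nm]] <- cl$merge_map
    }
  }
  encoded <- encode_categoricals(preds)
  parents <- encoded$data
  if (!ncol(parents)) stop("no usable predictors")
  for (nm in names(parents))
    if (anyNA(parents[[nm]])) stop("missing values in covariate '", nm, "'")

  covs <- lapply(names(parents), function(nm) {
    src <- encoded$source_map[nm]
    nu <- length(unique(parents[[nm]]))
    covariate(nm, if (!is.na(src) || nu <= 2) "binary" else "continuous",
              source = if (is.na(src)) nm else unname(src))
  })
  termset <- expand_terms(covs, k = k, poly = poly)

  pstd <- standardize_columns(as.matrix(parents))
  # binary parents (incl. dummies) enter term construction raw: products of
  # 0/1 indicators are joint-cell indicators, which is what the nzv filter
  # must see (a product of centered dummies takes four values with a benign
  # frequency ratio and could never be filtered); the design columns are
  # standardized afterwards either way
  is_binary <- vapply(covs, function(cv) cv$kind == "binary", logical(1))
  pstd$center[is_binary] <- 0
  pstd$scale[is_binary] <- 1
  pstd$x <- standardize_columns(as.matrix(parents), center = pstd$center,
                                scale = pstd$scale)$x
  parents_std <- as.data.frame(pstd$x, optional = TRUE, check.names = FALSE)

  # candidate design from standardized parents, then filter, then standardize
  raw_design <- build_design_matrix(parents_std, termset)
  vf <- variance_filter(raw_design, mode = filter,
                        freq_ratio = freq_ratio, unique_pct = unique_pct)
  keep <- vf$keep
  if (!length(keep)) stop("variance filter removed every candidate term")
  kept_terms <- termset$terms[termset$terms$id %in% keep, , drop = FALSE]
  kept_set <- structure(list(terms = kept_terms,
                             group_sizes = {
                               gs <- table(kept_terms$group_id)
                               setNames(as.integer(gs), names(gs))
                             },
                             k = k, poly = poly),
                        class = "term_set")
  dstd <- standardize_columns(raw_design[, keep, drop = FALSE])
  weights <- assign_penalty_weights(kept_set, gamma = gamma)

  # per-predictor training summaries (post-collapse scale) for effect profiles
  train_summary <- lapply(preds, function(x) {
    if (is.numeric(x) || is.logical(x)) {
      u <- sort(unique(as.numeric(x)))
      list(kind = "numeric", median = median(as.numeric(x)),
           range = range(as.numeric(x)),
           values = if (length(u) <= 12) u)
    } else {
      tab <- sort(table(x), decreasing = TRUE)
      list(kind = "categorical", mode = names(tab)[1], levels = names(tab))
    }
  })

  structure(list(
    x = dstd$x, y = y, y_levels = y_levels,
    target = target,
    termset = kept_set, full_termset = termset, weights = weights,
    dropped = vf$reasons,
    merge_maps = merge_maps, encoding = encoded$encoding,
    source_map = encoded$source_map,
    parent_center = pstd$center, parent_scale = pstd$scale,
    design_center = dstd$center, design_scale = dstd$scale,
    parent_names = names(parents),
    raw_predictors = setdiff(names(data), target),
    train_summary = train_summary,
    config = list(k = k, poly = poly, filter = filter,
                  rare_threshold = rare_threshold, gamma = gamma,
                  freq_ratio = freq_ratio, unique_pct = unique_pct)
  ), class = "srl_prep")
}

#' Apply a fitted recipe to new data
#'
#' Replays the stored preprocessing on `newdata` using training statistics
#' only: level merge maps, dummy encoding, parent standardization, term
#' construction, and design standardization.  Applying a recipe to its own
#' training data reproduces the training design exactly.
#'
#' @param prep An [srl_prep()] object.
#' @param newdata Data frame with the training predictor columns (the
#'   target column may be absent).
#' @return Numeric design matrix on the standardized training scale.
#' @export
bake_design <- function(prep, newdata) {
  miss <- setdiff(prep$raw_predictors, names(newdata))
  if (length(miss)) stop("newdata is missing columns: ",
                         paste(miss, collapse = ", "))
  preds <- newdata[prep$raw_predictors]
  for (nm in names(prep$merge_maps))
    preds[[nm]] <- collapse_rare_levels(preds[[nm]],
                                        merge_map = prep$merge_maps[[nm]])$values
  encoded <- encode_categoricals(preds, encoding = prep$encoding)
  parents <- encoded$data
  miss <- setdiff(prep$parent_names, names(parents))
  if (length(miss)) stop("encoding failed to produce columns: ",
                         paste(miss, collapse = ", "))
  parents <- parents[prep$parent_names]
  for (nm in names(parents))
    if (anyNA(parents[[nm]])) stop("missing values in covariate '", nm, "'")
  pstd <- standardize_columns(as.matrix(parents),
                              center = prep$parent_center,
                              scale = prep$parent_scale)
  raw_design <- build_design_matrix(
    as.data.frame(pstd$x, optional = TRUE, check.names = FALSE),
    prep$termset)
  std <- standardize_columns(raw_design, center = prep$design_center,
                             scale = prep$design_scale)
  std$x
}
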