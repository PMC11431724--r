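#' Describe a covariate
#'
#' A covariate is one column of the (post-encoding) predictor set.  Dummy
#' columns derived from the same categorical share a `source`, which stops
#' them from being multiplied together during term expansion (the product of
#' two dummies of one factor is identically zero or duplicates a dummy).
#'
#' @param name Column name; must be unique within a dataset.
#' @param kind One of `"continuous"`, `"binary"`, `"categorical"`.
#' @param levels Category labels (categorical only).
#' @param source Originating covariate (defaults to `name`); dummy columns
#'   from one categorical share their source.
#' @return A list of class `"covariate"`.
#' @export
covariate <- function(name, kind = c("continuous", "binary", "categorical"),
                      levels = NULL, source = name) {
  kind <- match.arg(kind)
  if (kind == "categorical" && (is.null(levels) || length(levels) < 2))
    stop("categorical covariates need at least 2 levels")
  structure(list(name = name, kind = kind, levels = levels, source = source),
            class = "covariate")
}

#' Infer covariate descriptors from a data frame
#'
#' Numeric columns with exactly two distinct observed values are classed as
#' binary; other numeric columns as continuous; factors and characters as
#' categorical.
#'
#' @param data A data frame of predictors.
#' @return A list of [covariate()] objects.
#' @export
infer_covariates <- function(data) {
  lapply(names(data), function(nm) {
    x <- data[[nm]]
    if (is.numeric(x) || is.logical(x)) {
      nu <- length(unique(x[!is.na(x)]))
      covariate(nm, if (nu <= 2) "binary" else "continuous")
    } else {
      covariate(nm, "categorical", levels = unique(as.character(x)))
    }
  })
}

#' Expand covariates into main, interaction and polynomial terms
#'
#' Builds the candidate term set `X = [A B C]`: all main effects (`A`), all
#' products of up to `k + 1` distinct covariates (`B`; with `k = 1`, all
#' pairwise interactions), and polynomial terms of orders `2..poly` for
#' continuous covariates (`C`).  Interaction ids are canonicalized by
#' sorting parent names, so `"x1:x2"` and `"x2:x1"` are the same term.
#' Dummy columns sharing a `source` are never multiplied together, and
#' binary covariates get no polynomial terms (x^2 = x under 0/1 coding).
#'
#' @param covariates A list of [covariate()] objects (or a data frame, which
#'   is passed through [infer_covariates()]).
#' @param k Maximum interaction argument: interactions involve up to `k + 1`
#'   distinct covariates.  `k = 0` disables interactions.
#' @param poly Maximum polynomial order; `poly = 1` disables polynomials.
#' @return An object of class `"term_set"`: a list with `terms` (data frame
#'   of id/kind/order/group_id plus a list-column of parents), `group_sizes`,
#'   `k`, `poly`.
#' @export
expand_terms <- function(covariates, k = 1, poly = 2) {
  if (is.data.frame(covariates)) covariates <- infer_covariates(covariates)
  if (k < 0 || poly < 1) stop("need k >= 0 and poly >= 1")
  nms <- vapply(covariates, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate covariate names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  kinds <- vapply(covariates, `[[`, "", "kind")
  srcs <- vapply(covariates, `[[`, "", "source")

  ord <- order(nms)
  mains <- data.frame(id = nms[ord], kind = "main", order = 1L,
                      group_id = "main", stringsAsFactors = FALSE)
  mains$parents <- as.list(nms[ord])

  inter <- list()
  p <- length(nms)
  if (k >= 1 && p >= 2) {
    for (m in 2:min(k + 1, p)) {
      combs <- utils::combn(sort(nms), m, simplify = FALSE)
      keep <- vapply(combs, function(cc) {
        s <- srcs[match(cc, nms)]
        !anyDuplicated(s)
      }, logical(1))
      combs <- combs[keep]
      if (!length(combs)) next
      ids <- vapply(combs, paste, "", collapse = ":")
      o <- order(ids)
      d <- data.frame(id = ids[o], kind = "interaction", order = m - 1L,
                      group_id = paste0("interaction", m - 1L),
                      stringsAsFactors = FALSE)
      d$parents <- combs[o]
      inter[[length(inter) + 1]] <- d
    }
  }

  polys <- list()
  if (poly >= 2) {
    cont <- sort(nms[kinds == "continuous"])
    for (m in 2:poly) {
      if (!length(cont)) break
      d <- data.frame(id = paste0(cont, "^", m), kind = "polynomial",
                      order = as.integer(m), group_id = paste0("poly", m),
                      stringsAsFactors = FALSE)
      d$parents <- as.list(cont)
      polys[[length(polys) + 1]] <- d
    }
  }

  terms <- do.call(rbind, c(list(mains), inter, polys))
  rownames(terms) <- NULL
  gs <- table(terms$group_id)
  structure(list(terms = terms,
                 group_sizes = setNames(as.integer(gs), names(gs)),
                 k = k, poly = poly),
            class = "term_set")
}

#' @export
print.term_set <- function(x, ...) {
  cat("Term set: ", nrow(x$terms), " terms (k = ", x$k, ", poly = ", x$poly,
      ")\n", sep = "")
  print(x$group_sizes)
  invisible(x)
}

#' Build the expanded design matrix for a term set
#'
#' One column per term: main columns are copied, interaction columns are
#' elementwise products of their parent columns, polynomial columns are
#' elementwise powers.  Column order matches the term set.
#'
#' @param data A data frame (or matrix) holding every parent covariate as a
#'   numeric column.  Categorical covariates must already be dummy-encoded.
#' @param termset A [expand_terms()] result, or its `terms` data frame.
#' @return A numeric matrix with term ids as column names.
#' @export
build_design_matrix <- function(data, termset) {
  terms <- if (inherits(termset, "term_set")) termset$terms else termset
  data <- as.data.frame(data)
  need <- unique(unlist(terms$parents))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  n <- nrow(data)
  for (nm in need) {
    x <- data[[nm]]
    if (!is.numeric(x)) stop("covariate '", nm, "' is not numeric; encode it first")
    if (anyNA(x)) stop("missing values in covariate '", nm, "'")
  }
  X <- matrix(0, n, nrow(terms), dimnames = list(NULL, terms$id))
  for (t in seq_len(nrow(terms))) {
    kind <- terms$kind[t]
    par <- terms$parents[[t]]
    X[, t] <- switch(kind,
      main = data[[par]],
      interaction = Reduce(`*`, lapply(par, function(nm) data[[nm]])),
      polynomial = data[[par]]^terms$order[t])
  }
  X
}

#' Assign ranked-sparsity penalty weights
#'
#' Each main effect and interaction gets weight `(size of its group)^gamma`;
#' a polynomial term of order `m` gets `(cumulative number of candidate
#' terms of polynomial order <= m, with mains counted at order 1)^gamma`.
#' With the default `gamma = 0.5` this calibrates the prior information
#' contributed by the whole block of interactions to match that of the
#' mains; `gamma = 0` gives unit weights, i.e. a plain lasso.
#'
#' @param termset An [expand_terms()] result.
#' @param gamma Nonnegative exponent on group size (default 0.5).
#' @param poly_weight_fun Optional hook replacing the cumulative-dimension
#'   rule for polynomial groups: a function `(order, termset) -> group size`
#'   whose result is raised to `gamma`.
#' @return An object of class `"penalty_weights"`: list with `weights`
#'   (named numeric, one per term), `gamma`, `unpenalized` (character,
#'   normally empty; the intercept is handled separately by the solver).
#' @export
assign_penalty_weights <- function(termset, gamma = 0.5,
                                   poly_weight_fun = NULL) {
  stopifnot(inherits(termset, "term_set"), gamma >= 0)
  terms <- termset$terms
  gs <- termset$group_sizes
  n_main <- sum(terms$kind == "main")
  w <- numeric(nrow(terms))
  for (t in seq_len(nrow(terms))) {
    if (terms$kind[t] == "polynomial") {
      m <- terms$order[t]
      size <- if (is.null(poly_weight_fun)) {
        n_main + sum(terms$kind == "polynomial" & terms$order <= m)
      } else {
        poly_weight_fun(m, termset)
      }
      w[t] <- size^gamma
    } else {
      w[t] <- gs[[terms$group_id[t]]]^gamma
    }
  }
  structure(list(weights = setNames(w, terms$id), gamma = gamma,
                 unpenalized = character(0)),
            class = "penalty_weights")
}
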