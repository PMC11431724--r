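#' Read a PMLB-format dataset
#'
#' Penn Machine Learning Benchmarks datasets are (optionally gzipped)
#' tab-separated files with a header row and a column literally named
#' `target`.  This reader works offline from a local file path.
#'
#' @param path Path to a `.tsv` or `.tsv.gz` file.
#' @param sep Field delimiter (default tab).
#' @return Data frame with a `target` column.
#' @export
read_pmlb <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE)
  if (!"target" %in% names(d))
    stop("not a PMLB dataset: no 'target' column in ", path)
  d
}

#' Read a local PMLB metadata cache
#'
#' Expects a CSV with at least `name`, `endpoint`, `n_obs`, `n_features`
#' and optionally `friedman`, as consumed by [filter_datasets()].  The
#' registry's own summary column names (`dataset`, `task`, `n_instances`,
#' `n_features`) are mapped if present.
#'
#' @param path Path to the CSV cache.
#' @return Metadata data frame.
#' @export
read_pmlb_metadata <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  ren <- c(dataset = "name", n_instances = "n_obs", task = "endpoint")
  for (old in names(ren))
    if (old %in% names(d) && !ren[[old]] %in% names(d))
      names(d)[names(d) == old] <- ren[[old]]
  if ("n_binary_features" %in% names(d) && "endpoint" %in% names(d)) {
    # registry encodes task as classification/regression; binary endpoints
    # are classification tasks with two target classes
    if ("n_classes" %in% names(d))
      d$endpoint <- ifelse(d$endpoint == "regression", "continuous",
                           ifelse(d$n_classes == 2, "binary", "categorical"))
  }
  d
}
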