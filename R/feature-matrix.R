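#' Feature matrix container
#'
#' A numeric matrix with one row per sequence, provenance-tagged column
#' names (e.g. `tfidf:ACG`, `base:gc_skew`, `pseknc:k3:lam1:twist`),
#' a binary label vector, and per-column method tags.
#'
#' @param x numeric matrix; column names must be unique and non-missing.
#' @param labels factor/character of `positive`/`negative`, one per row.
#' @param method character vector of per-column method tags (recycled).
#' @return object of class `feature_matrix`: list with `x`, `labels`,
#'   `method`.
#' @export
feature_matrix <- function(x, labels, method = "unknown") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("feature columns must have unique names")
  if (nrow(x) != length(labels))
    stop("row count must equal label count")
  if (anyNA(x)) stop("feature matrix contains missing values")
  labels <- factor(as.character(labels), levels = c("positive", "negative"))
  if (anyNA(labels)) stop("labels must be 'positive' or 'negative'")
  method <- rep_len(method, ncol(x))
  structure(list(x = x, labels = labels, method = method),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d sequences x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(unique(x$method), collapse = "+")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

# Column subset, preserving labels and method tags.
fm_select <- function(fm, cols) {
  feature_matrix(fm$x[, cols, drop = FALSE], fm$labels, fm$method[cols])
}

# Column-wise concatenation of feature matrices over the same rows.
fm_cbind <- function(...) {
  fms <- list(...)
  labs <- fms[[1]]$labels
  for (f in fms[-1])
    if (!identical(as.character(f$labels), as.character(labs)))
      stop("cannot concatenate feature matrices with differing labels")
  feature_matrix(do.call(cbind, lapply(fms, `[[`, "x")), labs,
                 unlist(lapply(fms, `[[`, "method")))
}

#' Write / read a feature matrix as TSV
#'
#' Full double precision is preserved (values are printed with 17
#' significant digits), so a round-trip is bit-identical.
#'
#' @param fm a [feature_matrix()].
#' @param path TSV path. Columns: `id` (rownames if present), one column
#'   per feature, and a trailing `label` column.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns a `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(format(fm$x, digits = 17, scientific = TRUE, trim = TRUE),
                      optional = TRUE, stringsAsFactors = FALSE)
  df <- cbind(id = if (is.null(rownames(fm$x))) as.character(seq_len(nrow(fm$x))) else rownames(fm$x),
              df, label = as.character(fm$labels))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method\t", paste(fm$method, collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "# method\t"))
    stop("not a feature matrix TSV (missing method header): ", path)
  method <- strsplit(sub("^# method\t", "", header), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  labs <- df$label
  ids <- df$id
  df$label <- NULL; df$id <- NULL
  x <- as.matrix(df)
  rownames(x) <- ids
  feature_matrix(x, labs, method)
}
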