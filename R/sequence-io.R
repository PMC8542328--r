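#' Labeled DNA sequence sets
#'
#' A `labeled_seq_set` holds fixed-length DNA windows for one species,
#' labeled `positive` (replication origin) or `negative` (background).
#' It is the unit every pipeline stage consumes.
#'
#' @param ids character vector of unique record ids.
#' @param sequences character vector of DNA sequences over `{A,C,G,T,N}`
#'   (lower case accepted, stored upper case).
#' @param labels character/factor vector with values `"positive"` /
#'   `"negative"`.
#' @param species species tag.
#' @param cell_type optional cell-type tag.
#' @return An object of class `labeled_seq_set`: a list with elements
#'   `records` (data.frame with columns `id`, `sequence`, `label`),
#'   `species` and `cell_type`.
#' @export
labeled_seq_set <- function(ids, sequences, labels, species = "unknown",
                            cell_type = NULL) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  labels <- as.character(labels)
  if (length(ids) != length(sequences) || length(ids) != length(labels))
    stop("ids, sequences and labels must have equal length")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!all(labels %in% c("positive", "negative")))
    stop("labels must be 'positive' or 'negative'")
  if (any(!nzchar(sequences)))
    stop("empty sequence for id: ", paste(ids[!nzchar(sequences)], collapse = ", "))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N} for id: ",
         paste(ids[bad], collapse = ", "))
  structure(
    list(
      records = data.frame(id = ids, sequence = sequences,
                           label = factor(labels, levels = c("positive", "negative")),
                           stringsAsFactors = FALSE),
      species = species,
      cell_type = cell_type
    ),
    class = "labeled_seq_set"
  )
}

#' @export
print.labeled_seq_set <- function(x, ...) {
  n <- label_counts(x)
  cat(sprintf("labeled_seq_set: %d sequences (%d positive, %d negative), species '%s'\n",
              nrow(x$records), n[["positive"]], n[["negative"]], x$species))
  lens <- range(nchar(x$records$sequence))
  cat(sprintf("  lengths: %d..%d bp\n", lens[1], lens[2]))
  invisible(x)
}

#' @export
length.labeled_seq_set <- function(x) nrow(x$records)

#' Per-label record counts
#'
#' @param set a `labeled_seq_set`.
#' @return named integer vector with elements `positive` and `negative`.
#' @export
label_counts <- function(set) {
  stopifnot(inherits(set, "labeled_seq_set"))
  tab <- table(set$records$label)
  c(positive = as.integer(tab[["positive"]]),
    negative = as.integer(tab[["negative"]]))
}

# Subset a labeled_seq_set by record index, keeping metadata.
subset_set <- function(set, idx) {
  out <- set
  out$records <- set$records[idx, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

read_fasta_chars <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) stop("malformed FASTA in '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  if (length(x) == 0) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(x))
  ids <- sub("\\s.*$", "", names(x))
  names(seqs) <- NULL
  list(ids = ids, sequences = seqs)
}

#' Read a labeled sequence set from a positive and a negative FASTA file
#'
#' Labels follow the two-file convention used by published origin
#' benchmarks: every record in `positive_path` is an origin window, every
#' record in `negative_path` background. Sequences are upper-cased; any
#' character outside `{A,C,G,T,N}` is rejected with the offending id.
#'
#' @param positive_path FASTA file of positive (origin) sequences.
#' @param negative_path FASTA file of negative sequences.
#' @param species species tag stored on the set.
#' @param cell_type optional cell-type tag.
#' @param expected_length if non-`NULL`, sequences whose length differs
#'   trigger a warning (`warn_only = TRUE`, default) or an error.
#'   Benchmarks in this field use 300 bp windows, but the method itself
#'   does not require it.
#' @param warn_only treat length mismatches as warnings rather than errors.
#' @return a [labeled_seq_set()].
#' @export
read_labeled_fasta <- function(positive_path, negative_path, species = "unknown",
                               cell_type = NULL, expected_length = 300,
                               warn_only = TRUE) {
  pos <- read_fasta_chars(positive_path)
  neg <- read_fasta_chars(negative_path)
  dup <- intersect(pos$ids, neg$ids)
  if (length(dup))
    stop("duplicate id across positive and negative files: ",
         paste(dup, collapse = ", "))
  set <- labeled_seq_set(
    ids = c(pos$ids, neg$ids),
    sequences = c(pos$sequences, neg$sequences),
    labels = rep(c("positive", "negative"), c(length(pos$ids), length(neg$ids))),
    species = species, cell_type = cell_type
  )
  if (!is.null(expected_length)) {
    off <- nchar(set$records$sequence) != expected_length
    if (any(off)) {
      msg <- sprintf("%d of %d sequences differ from expected length %d bp",
                     sum(off), nrow(set$records), expected_length)
      if (warn_only) warning(msg) else stop(msg)
    }
  }
  set
}

#' Write a labeled sequence set back to two FASTA files
#'
#' Inverse of [read_labeled_fasta()]: round-tripping reproduces the set.
#'
#' @param set a `labeled_seq_set`.
#' @param positive_path,negative_path output FASTA paths.
#' @return invisibly, the two paths.
#' @export
write_labeled_fasta <- function(set, positive_path, negative_path) {
  stopifnot(inherits(set, "labeled_seq_set"))
  for (lab in c("positive", "negative")) {
    rec <- set$records[set$records$label == lab, , drop = FALSE]
    x <- Biostrings::DNAStringSet(rec$sequence)
    names(x) <- rec$id
    Biostrings::writeXStringSet(
      x, if (lab == "positive") positive_path else negative_path)
  }
  invisible(c(positive_path, negative_path))
}

#' Stratified train/test split
#'
#' Holds out `floor(n_label * test_fraction)` records per label class, so
#' the split is stratified and deterministic for a fixed seed. Benchmarks
#' in this field use an 8:2 split (`test_fraction = 0.2`).
#'
#' @param set a `labeled_seq_set`.
#' @param test_fraction proportion in (0, 1) held out per class.
#' @param seed integer seed controlling which records are held out.
#' @return list with elements `train` and `test`, both `labeled_seq_set`s
#'   partitioning the input.
#' @export
split_train_test <- function(set, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(set, "labeled_seq_set"))
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must be in (0, 1)")
  cnt <- label_counts(set)
  if (any(cnt < 2))
    stop("each label class needs at least 2 members to split")
  lab <- set$records$label
  test_idx <- integer(0)
  rng <- local_rng(seed)
  for (lv in levels(lab)) {
    idx <- which(lab == lv)
    n_test <- floor(length(idx) * test_fraction)
    if (n_test > 0)
      test_idx <- c(test_idx, rng$sample(idx, n_test))
  }
  list(train = subset_set(set, setdiff(seq_along(lab), test_idx)),
       test = subset_set(set, sort(test_idx)))
}

#' Write a split manifest
#'
#' Records id -> partition as a two-column TSV beside a split, for
#' reproducibility audits.
#'
#' @param split a list with `train` and `test` as returned by
#'   [split_train_test()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_split_manifest <- function(split, path) {
  df <- rbind(
    data.frame(id = split$train$records$id, partition = "train"),
    data.frame(id = split$test$records$id, partition = "test")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Seed-scoped RNG: runs sampling under a private seed without disturbing the
# caller's .Random.seed.
local_rng <- function(seed) {
  seed <- as.integer(seed)
  env <- new.env()
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(env$state)
    res <- expr_fun()
    env$state <- env$state + 1L
    res
  }
  env$state <- seed
  list(sample = function(x, size) run(function() sample(x, size)))
}
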