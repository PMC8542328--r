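#' Fit a k-tuple TF-IDF model on a training set
#'
#' Term frequency is class-conditional: \eqn{tf_i} is the count of tuple
#' i summed over the POSITIVE training sequences, divided by the total
#' count of all vocabulary tuples in the positive corpus (so
#' \eqn{\sum_i tf_i = 1}). Inverse document frequency uses all training
#' sequences of both classes:
#' \deqn{IDF_i = \log\left(\frac{|D|}{1 + |\{j : t_i \in d_j\}|}\right)}
#' with the +1 guarding against an empty document set. The per-tuple
#' score is the elementwise product \eqn{tfidf_i = tf_i \cdot IDF_i}.
#' Note IDF is negative for tuples present in every sequence
#' (\eqn{\log(|D|/(1+|D|)) < 0}); the formula is kept verbatim, not
#' clamped. The model is frozen at fit time: transforming new data never
#' alters it, so fitting inside each CV training fold is leakage-safe.
#'
#' @param train a [labeled_seq_set()] with at least one positive and one
#'   negative sequence.
#' @param vocab a [kmer_vocabulary()] (default k = 1..6, 5460 tuples).
#' @param log_base base of the IDF logarithm; natural log by default
#'   (ranking is monotone in the base).
#' @return object of class `tfidf_model`: list with `tf`, `idf`, `tfidf`
#'   (numeric vectors over the vocabulary), `doc_frequency`,
#'   `n_documents`, `vocab`, `log_base`.
#' @export
fit_tfidf <- function(train, vocab = kmer_vocabulary(1L, 6L), log_base = exp(1)) {
  stopifnot(inherits(train, "labeled_seq_set"), inherits(vocab, "kmer_vocabulary"))
  cnt <- label_counts(train)
  if (cnt[["positive"]] < 1)
    stop("fit_tfidf requires at least one positive training sequence")
  counts <- count_kmer_matrix(train, vocab)
  pos <- train$records$label == "positive"
  pos_total <- colSums(counts[pos, , drop = FALSE])
  denom <- sum(pos_total)
  if (denom == 0)
    stop("positive corpus contains no countable tuples")
  tf <- pos_total / denom
  doc_freq <- colSums(counts > 0L)
  n_doc <- nrow(counts)
  idf <- log(n_doc / (1 + doc_freq), base = log_base)
  structure(
    list(tf = tf, idf = idf, tfidf = tf * idf,
         doc_frequency = as.integer(doc_freq), n_documents = n_doc,
         vocab = vocab, log_base = log_base),
    class = "tfidf_model"
  )
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat(sprintf("tfidf_model: %d tuples (k = %d..%d), fitted on %d sequences\n",
              length(x$tf), x$vocab$k_min, x$vocab$k_max, x$n_documents))
  invisible(x)
}

#' Transform sequences with a frozen TF-IDF model
#'
#' Each sequence s becomes the vector \eqn{l_i = tfidf_i \cdot n_i(s)}
#' where \eqn{n_i(s)} is the overlapping-window count of tuple i in s.
#' Model parameters are never refitted here; train and test data are
#' transformed identically.
#'
#' @param model a fitted [fit_tfidf()] model.
#' @param set a [labeled_seq_set()] to encode.
#' @param vocab optional vocabulary; must match the model's (size and
#'   ordering) if supplied.
#' @return a [feature_matrix()] with one `tfidf:`-tagged column per tuple.
#' @export
transform_tfidf <- function(model, set, vocab = NULL) {
  stopifnot(inherits(model, "tfidf_model"), inherits(set, "labeled_seq_set"))
  if (!is.null(vocab) &&
      !identical(vocab$entries, model$vocab$entries))
    stop("vocabulary mismatch: supplied vocabulary differs from the model's")
  counts <- count_kmer_matrix(set, model$vocab)
  x <- sweep(counts, 2, model$tfidf, `*`)
  colnames(x) <- paste0("tfidf:", model$vocab$entries)
  feature_matrix(x, labels = set$records$label,
                 method = rep("tfidf", ncol(x)))
}
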