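#' k-tuple vocabulary
#'
#' Ordered index of all k-tuples over `{A,C,G,T}` for k in
#' `[k_min, k_max]`: ascending k, lexicographic within k. For the default
#' range k = 1..6 the vocabulary has
#' \eqn{\sum_{k=1}^{6} 4^k = 5460} entries — the full index the TF-IDF
#' encoder scores.
#'
#' @param k_min,k_max tuple-size range, `1 <= k_min <= k_max`.
#' @return object of class `kmer_vocabulary`: list with `k_min`, `k_max`,
#'   `entries` (character vector), `k_of` (tuple size per entry).
#' @export
kmer_vocabulary <- function(k_min = 1L, k_max = 6L) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (!(k_min >= 1 && k_min <= k_max))
    stop("need 1 <= k_min <= k_max")
  total <- sum(4^(k_min:k_max))
  if (total > 5e6)
    stop(sprintf("vocabulary would have %.3g entries; refusing (> 5e6)", total))
  entries <- character(0); k_of <- integer(0)
  for (k in k_min:k_max) {
    # expand.grid varies the first factor fastest; order so the LAST
    # position varies fastest, giving lexicographic order within k
    g <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                     stringsAsFactors = FALSE)[, k:1, drop = FALSE]
    ent <- do.call(paste0, g)
    ord <- order(ent)
    entries <- c(entries, ent[ord])
    k_of <- c(k_of, rep(k, length(ent)))
  }
  structure(list(k_min = k_min, k_max = k_max, entries = entries, k_of = k_of),
            class = "kmer_vocabulary")
}

#' @export
print.kmer_vocabulary <- function(x, ...) {
  cat(sprintf("kmer_vocabulary: k = %d..%d, %d entries\n",
              x$k_min, x$k_max, length(x$entries)))
  invisible(x)
}

#' @export
length.kmer_vocabulary <- function(x) length(x$entries)

#' Count k-tuples with overlapping windows
#'
#' Counts every overlapping window of each tuple size in the vocabulary.
#' Windows containing `N` contribute to no entry (counts are never
#' imputed). A sequence shorter than a tuple size yields zeros for that
#' size. For a pure-ACGT sequence of length L, counts for tuple size k
#' total L - k + 1.
#'
#' @param sequence DNA string over `{A,C,G,T,N}` (case-insensitive).
#' @param vocab a [kmer_vocabulary()].
#' @return named integer vector aligned to `vocab$entries`.
#' @export
count_kmers <- function(sequence, vocab) {
  stopifnot(inherits(vocab, "kmer_vocabulary"))
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  x <- Biostrings::DNAString(sequence)
  counts <- integer(length(vocab$entries))
  names(counts) <- vocab$entries
  for (k in vocab$k_min:vocab$k_max) {
    if (nchar(sequence) < k) next
    # oligonucleotideFrequency tabulates ACGT-only windows, silently
    # dropping any window containing N — exactly the contract we need
    f <- Biostrings::oligonucleotideFrequency(x, width = k)
    counts[names(f)] <- as.integer(f)
  }
  counts
}

# Count matrix for all sequences in a set: rows = sequences, cols = vocab.
count_kmer_matrix <- function(set, vocab) {
  stopifnot(inherits(set, "labeled_seq_set"))
  xs <- Biostrings::DNAStringSet(set$records$sequence)
  out <- matrix(0L, nrow = length(xs), ncol = length(vocab$entries),
                dimnames = list(set$records$id, vocab$entries))
  for (k in vocab$k_min:vocab$k_max) {
    f <- Biostrings::oligonucleotideFrequency(xs, width = k)
    out[, colnames(f)] <- f
  }
  out
}
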