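# Independent oracles, deliberately naive: each re-derives a quantity by
# direct enumeration so the implementation under test is never checked
# against itself.

# O(L * |vocab|) substring scan; windows containing N match no tuple.
naive_count_oracle <- function(sequence, entries) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  vapply(entries, function(kmer) {
    k <- nchar(kmer)
    if (L < k) return(0L)
    hits <- 0L
    for (i in seq_len(L - k + 1))
      if (substr(sequence, i, i + k - 1) == kmer) hits <- hits + 1L
    hits
  }, integer(1))
}

# Sliding-window motif occurrence count (overlaps allowed).
count_motif_oracle <- function(sequence, motif) {
  naive_count_oracle(sequence, motif)[[1]]
}

# Textbook two-class F-score (Chen & Lin), coded independently with
# explicit loops.
fscore_oracle <- function(x, y_pos) {
  vapply(seq_len(ncol(x)), function(i) {
    xp <- x[y_pos, i]; xn <- x[!y_pos, i]
    num <- (mean(xp) - mean(x[, i]))^2 + (mean(xn) - mean(x[, i]))^2
    den <- sum((xp - mean(xp))^2) / (length(xp) - 1) +
           sum((xn - mean(xn))^2) / (length(xn) - 1)
    num / den
  }, numeric(1))
}

# Standard confusion-matrix Matthews correlation.
mcc_standard_oracle <- function(tp, fn, tn, fp) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / den
}

# AUC by exhaustive positive-negative pair enumeration (ties count 1/2).
auc_pairs_oracle <- function(pos, scores) {
  sp <- scores[pos]; sn <- scores[!pos]
  total <- 0
  for (a in sp) for (b in sn)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(sp) * length(sn))
}

# Brute-force series-correlation factors theta_{j,q} for a pure-ACGT
# sequence and a standardized property matrix H (16 x Lambda).
theta_oracle <- function(sequence, H, lam) {
  L <- nchar(sequence)
  di <- function(m) substr(sequence, m, m + 1)
  out <- matrix(0, lam, ncol(H))
  for (j in seq_len(lam)) {
    for (q in seq_len(ncol(H))) {
      s <- 0
      for (m in seq_len(L - j - 1))
        s <- s + H[di(m), q] * H[di(m + j), q]
      out[j, q] <- s / (L - j - 1)
    }
  }
  out
}

random_dna <- function(L, with_n = FALSE) {
  alph <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alph, L, replace = TRUE), collapse = "")
}

# Small labeled set builders used across test files.
toy_set <- function(pos, neg, species = "toy") {
  labeled_seq_set(
    ids = c(sprintf("p%d", seq_along(pos)), sprintf("n%d", seq_along(neg))),
    sequences = c(pos, neg),
    labels = rep(c("positive", "negative"), c(length(pos), length(neg))),
    species = species
  )
}

write_fasta_file <- function(ids, seqs, path, width = NULL) {
  lines <- unlist(mapply(function(id, s) {
    body <- if (is.null(width)) s else {
      starts <- seq(1, nchar(s), by = width)
      vapply(starts, function(i) substr(s, i, min(i + width - 1, nchar(s))), "")
    }
    c(paste0(">", id), body)
  }, ids, seqs, SIMPLIFY = FALSE))
  writeLines(lines, path)
  path
}
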