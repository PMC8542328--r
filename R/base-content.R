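#' Base-composition features of a sequence
#'
#' Four per-sequence scalars built from single-nucleotide counts
#' (N bases are excluded from all counts):
#' \itemize{
#'   \item AT-profile = (A+T) / (A+T+G+C)
#'   \item GC-profile = (G+C) / (A+T+G+C)
#'   \item GC-skew = (G-C) / (G+C)
#'   \item AT-skew = (A-T) / (A+T)
#' }
#' Strand-compositional skews of this kind are enriched near replication
#' origins, which is why four numbers can already carry signal.
#' Degenerate denominators (a sequence with no G/C, or no A/T) yield a
#' skew of 0 with `degenerate = TRUE`, rather than an error, so short toy
#' inputs remain usable.
#'
#' @param sequence DNA string over `{A,C,G,T,N}`.
#' @return named list: `at_profile`, `gc_profile`, `gc_skew`, `at_skew`
#'   (numeric scalars) and `degenerate` (logical flag).
#' @export
base_content <- function(sequence) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  f <- Biostrings::letterFrequency(Biostrings::DNAString(sequence),
                                   letters = c("A", "C", "G", "T"))
  a <- f[["A"]]; c_ <- f[["C"]]; g <- f[["G"]]; t <- f[["T"]]
  total <- a + c_ + g + t
  if (total == 0) stop("sequence has no countable (non-N) bases")
  degenerate <- FALSE
  gc_skew <- if (g + c_ > 0) (g - c_) / (g + c_) else { degenerate <- TRUE; 0 }
  at_skew <- if (a + t > 0) (a - t) / (a + t) else { degenerate <- TRUE; 0 }
  list(at_profile = (a + t) / total,
       gc_profile = (g + c_) / total,
       gc_skew = gc_skew,
       at_skew = at_skew,
       degenerate = degenerate)
}

# Base-content features for a whole set, as a feature_matrix (n x 4).
base_content_matrix <- function(set) {
  stopifnot(inherits(set, "labeled_seq_set"))
  vals <- t(vapply(set$records$sequence, function(s) {
    b <- base_content(s)
    c(b$at_profile, b$gc_profile, b$gc_skew, b$at_skew)
  }, numeric(4)))
  colnames(vals) <- paste0("base:", c("at_profile", "gc_profile",
                                      "gc_skew", "at_skew"))
  rownames(vals) <- set$records$id
  feature_matrix(vals, set$records$label, method = rep("base_content", 4))
}
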