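#' Specification for a synthetic origin/background sequence set
#'
#' The generator states a simple statistical world: both classes draw
#' i.i.d. bases from per-class composition vectors; positives may carry
#' planted copies of a short motif (inserted by overwriting, so all
#' sequences keep the stated length) and/or a compositional skew offset.
#' This is exactly the structure the package's features measure — motif
#' enrichment and GC/AT skew — with no attempt to imitate real
#' origin-recognition biology.
#'
#' Skew offsets are realized analytically: for a target GC-skew s at
#' GC-profile p, the base probabilities are P(G) = p(1+s)/2 and
#' P(C) = p(1-s)/2 (and symmetrically for AT-skew), so the expected
#' per-sequence skew equals the target.
#'
#' @param n_positive,n_negative class sizes.
#' @param length sequence length in bp (default 300, the benchmark
#'   window size in this field).
#' @param background length-4 probability vector over A,C,G,T shared by
#'   both classes before offsets (default uniform).
#' @param background_positive optional length-4 probability vector for
#'   the positive class only (e.g. to compensate the compositional
#'   footprint of a planted motif); defaults to `background`. Skew
#'   offsets are applied on top of it.
#' @param motif DNA string planted in positives (default "GGG", a motif
#'   reported enriched at origins of several species; "" disables).
#' @param planting_rate probability a positive sequence receives copies.
#' @param copies motif copies per planted sequence (non-overlapping).
#' @param gc_skew_offset,at_skew_offset skew added to the POSITIVE
#'   class's composition relative to the background.
#' @param seed integer seed; generation is deterministic per seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_positive = 200L, n_negative = 200L,
                           length = 300L,
                           background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                           background_positive = NULL,
                           motif = "GGG", planting_rate = 1, copies = 3L,
                           gc_skew_offset = 0, at_skew_offset = 0,
                           seed = 1L) {
  check_probs <- function(p, what) {
    p <- unname(p)
    if (length(p) != 4 || abs(sum(p) - 1) > 1e-8 || any(p < 0))
      stop(what, " must be 4 probabilities over A,C,G,T summing to 1")
    p
  }
  background <- check_probs(background, "background")
  if (!is.null(background_positive))
    background_positive <- check_probs(background_positive, "background_positive")
  motif <- toupper(motif)
  if (nzchar(motif) && grepl("[^ACGT]", motif))
    stop("motif must be over {A,C,G,T}")
  if (nchar(motif) >= length) stop("motif length must be < sequence length")
  if (planting_rate < 0 || planting_rate > 1)
    stop("planting_rate must be in [0, 1]")
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 length = as.integer(length), background = background,
                 background_positive = background_positive,
                 motif = motif, planting_rate = planting_rate,
                 copies = as.integer(copies),
                 gc_skew_offset = gc_skew_offset,
                 at_skew_offset = at_skew_offset, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Re-weight a composition vector (A,C,G,T) to shift its expected skews.
skewed_probs <- function(p, gc_skew_offset, at_skew_offset) {
  p_at <- p[1] + p[4]; p_gc <- p[2] + p[3]
  s_gc <- if (p_gc > 0) (p[3] - p[2]) / p_gc else 0
  s_at <- if (p_at > 0) (p[1] - p[4]) / p_at else 0
  s_gc <- max(-1, min(1, s_gc + gc_skew_offset))
  s_at <- max(-1, min(1, s_at + at_skew_offset))
  c(p_at * (1 + s_at) / 2,   # A
    p_gc * (1 - s_gc) / 2,   # C
    p_gc * (1 + s_gc) / 2,   # G
    p_at * (1 - s_at) / 2)   # T
}

# Non-overlapping start positions for `copies` intervals of width ml in
# 1..L: sample sorted combinations, then spread by (i-1)*(ml-1).
motif_starts <- function(L, ml, copies) {
  slots <- L - copies * ml + copies
  if (slots < copies)
    stop(sprintf("cannot fit %d non-overlapping copies of a %d bp motif in %d bp",
                 copies, ml, L))
  u <- sort(sample.int(slots, copies))
  u + (seq_len(copies) - 1L) * (ml - 1L)
}

#' Generate a labeled synthetic sequence set
#'
#' @param spec a [synthetic_spec()].
#' @param species species tag for the resulting set.
#' @return a [labeled_seq_set()] with `n_positive + n_negative`
#'   sequences of the stated length; byte-identical for a fixed spec.
#' @export
generate_synthetic <- function(spec, species = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  bases <- c("A", "C", "G", "T")
  p_neg <- spec$background
  p_pos <- skewed_probs(spec$background_positive %||% spec$background,
                        spec$gc_skew_offset, spec$at_skew_offset)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  draw <- function(probs) paste(sample(bases, spec$length, replace = TRUE,
                                       prob = probs), collapse = "")
  mchars <- strsplit(spec$motif, "")[[1]]
  ml <- length(mchars)
  pos_seqs <- vapply(seq_len(spec$n_positive), function(i) {
    s <- strsplit(draw(p_pos), "")[[1]]
    if (ml > 0 && spec$copies > 0 && stats::runif(1) < spec$planting_rate) {
      for (st in motif_starts(spec$length, ml, spec$copies))
        s[st:(st + ml - 1)] <- mchars
    }
    paste(s, collapse = "")
  }, character(1))
  neg_seqs <- vapply(seq_len(spec$n_negative), function(i) draw(p_neg),
                     character(1))
  labeled_seq_set(
    ids = c(sprintf("pos_%04d", seq_len(spec$n_positive)),
            sprintf("neg_%04d", seq_len(spec$n_negative))),
    sequences = c(pos_seqs, neg_seqs),
    labels = rep(c("positive", "negative"),
                 c(spec$n_positive, spec$n_negative)),
    species = species
  )
}

#' Generate two synthetic "species"
#'
#' Supports cross-species transfer experiments: shared motifs between
#' the specs give transferable signal, disjoint motifs do not.
#'
#' @param spec_a,spec_b [synthetic_spec()]s; identical specs (including
#'   seed) trigger a warning since the sets would coincide.
#' @param species names for the two sets.
#' @return list of two [labeled_seq_set()]s.
#' @export
two_species <- function(spec_a, spec_b,
                        species = c("synthetic_A", "synthetic_B")) {
  if (identical(unclass(spec_a), unclass(spec_b)))
    warning("identical specs and seeds: the two species will coincide")
  list(generate_synthetic(spec_a, species[1]),
       generate_synthetic(spec_b, species[2]))
}

#' Write a synthetic set as the two-file FASTA convention
#'
#' Emits positive/negative FASTA files plus a JSON provenance sidecar
#' recording the full spec (seed included), so every generated fixture
#' is reproducible from its sidecar alone.
#'
#' @param spec a [synthetic_spec()].
#' @param positive_path,negative_path,sidecar_path output paths.
#' @param species species tag.
#' @return invisibly, the generated [labeled_seq_set()].
#' @export
generate_to_fasta <- function(spec, positive_path, negative_path,
                              sidecar_path = NULL, species = "synthetic") {
  set <- generate_synthetic(spec, species)
  write_labeled_fasta(set, positive_path, negative_path)
  if (!is.null(sidecar_path))
    jsonlite::write_json(unclass(spec), sidecar_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(set)
}
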