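#' PseKNC-II (series correlation) configuration
#'
#' Series-correlation pseudo k-tuple nucleotide composition augments the
#' normalized k-tuple frequency vector with tiered correlation factors
#' computed separately for each physicochemical dinucleotide property.
#' Each property is z-score standardized over the 16 dinucleotides before
#' use (mean 0, sd 1).
#'
#' @param k tuple size (scalar) for the composition part.
#' @param lam number of correlation tiers \eqn{\lambda \ge 0}; tier j
#'   correlates dinucleotides j steps apart, so sequences must satisfy
#'   \eqn{\lambda < L - k}.
#' @param w weight factor in (0, 1] balancing composition against
#'   correlation terms.
#' @param properties either a character vector naming columns of the
#'   packaged property table (twist, tilt, roll, shift, slide, rise), or
#'   a numeric matrix with 16 rows named by dinucleotide and one column
#'   per property (raw values; standardization is applied here).
#' @return object of class `pseknc_config`: `k`, `lam`, `w`, `H`
#'   (standardized 16 x Lambda property matrix).
#' @export
pseknc_config <- function(k = 2L, lam = 2L, w = 0.5,
                          properties = c("twist", "tilt", "roll",
                                         "shift", "slide", "rise")) {
  k <- as.integer(k); lam <- as.integer(lam)
  if (lam < 0) stop("lam must be >= 0")
  if (!(w > 0 && w <= 1)) stop("w must be in (0, 1]")
  if (is.character(properties)) {
    tab <- dinucleotide_properties()
    unknown <- setdiff(properties, colnames(tab))
    if (length(unknown))
      stop("unknown property name(s): ", paste(unknown, collapse = ", "))
    H <- tab[, properties, drop = FALSE]
  } else {
    H <- as.matrix(properties)
    if (nrow(H) != 16 || is.null(rownames(H)))
      stop("property matrix must have 16 dinucleotide-named rows")
    H <- H[order(rownames(H)), , drop = FALSE]
  }
  # z-standardize each property over the 16 dinucleotides
  H <- scale(H)
  attr(H, "scaled:center") <- NULL
  attr(H, "scaled:scale") <- NULL
  structure(list(k = k, lam = lam, w = w, H = H), class = "pseknc_config")
}

#' Packaged dinucleotide property table
#'
#' Raw (unstandardized) B-DNA step parameters for the 16 dinucleotides;
#' see the file header of `extdata/dinucleotide_properties.tsv` for
#' provenance. Users may substitute their own table in [pseknc_config()].
#'
#' @return 16 x 6 numeric matrix, rows named by dinucleotide.
#' @export
dinucleotide_properties <- function() {
  path <- system.file("extdata", "dinucleotide_properties.tsv",
                      package = "oriclass", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$dinucleotide
  m[order(rownames(m)), , drop = FALSE]
}

#' PseKNC-II encoding of one sequence
#'
#' Produces a vector of length \eqn{4^k + \lambda\Lambda}. With
#' \eqn{f_u} the normalized k-tuple frequencies (summing to 1) and
#' correlation factors
#' \deqn{\theta_{j,q} = \frac{1}{L-j-1} \sum_{m=1}^{L-j-1}
#'   H_q(s_m s_{m+1})\, H_q(s_{m+j} s_{m+j+1})}
#' for tier j = 1..\eqn{\lambda} and property q = 1..\eqn{\Lambda}, the
#' entries are
#' \deqn{d_u = \frac{f_u}{\sum f + w \sum \theta} \quad (u \le 4^k),
#'   \qquad d_{4^k+(j-1)\Lambda+q} = \frac{w\,\theta_{j,q}}
#'   {\sum f + w \sum \theta}.}
#' The full vector always sums to 1 (shared normalizer); with
#' \eqn{\lambda = 0} it reduces exactly to the normalized k-tuple
#' composition. Windows or dinucleotide pairs containing N are skipped;
#' the correlation average divides by the number of valid pairs.
#'
#' @param sequence DNA string over `{A,C,G,T,N}` of length L with
#'   \eqn{\lambda < L - k}.
#' @param config a [pseknc_config()].
#' @return named numeric vector of length `4^k + lam * ncol(H)`.
#' @export
pseknc2 <- function(sequence, config) {
  stopifnot(inherits(config, "pseknc_config"))
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  L <- nchar(sequence)
  k <- config$k; lam <- config$lam; w <- config$w; H <- config$H
  if (lam >= L - k)
    stop(sprintf("lam (%d) must be < L - k = %d", lam, L - k))
  vocab <- kmer_vocabulary(k, k)
  n <- count_kmers(sequence, vocab)
  tot <- sum(n)
  if (tot == 0) stop("no countable k-tuples (sequence too short or all N)")
  f <- n / tot

  nprop <- ncol(H)
  theta <- matrix(0, nrow = lam, ncol = nprop,
                  dimnames = list(NULL, colnames(H)))
  if (lam > 0) {
    chars <- strsplit(sequence, "")[[1]]
    dinucs <- paste0(chars[-L], chars[-1])          # L-1 dinucleotides
    hv <- matrix(NA_real_, nrow = L - 1, ncol = nprop)
    ok <- dinucs %in% rownames(H)
    hv[ok, ] <- H[dinucs[ok], , drop = FALSE]
    for (j in seq_len(lam)) {
      m_max <- L - j - 1                            # pairs (m, m+j) of dinucs
      a <- hv[seq_len(m_max), , drop = FALSE]
      b <- hv[seq_len(m_max) + j, , drop = FALSE]
      prod_ <- a * b
      valid <- stats::complete.cases(prod_)
      if (!any(valid))
        stop(sprintf("no valid dinucleotide pairs at tier %d (too many N)", j))
      theta[j, ] <- colSums(prod_[valid, , drop = FALSE]) / sum(valid)
    }
  }
  denom <- sum(f) + w * sum(theta)
  d_comp <- f / denom
  out <- c(d_comp,
           if (lam > 0) w * as.vector(t(theta)) / denom else numeric(0))
  nm_theta <- if (lam > 0)
    paste0("lam", rep(seq_len(lam), each = nprop), ":",
           rep(colnames(H), lam)) else character(0)
  names(out) <- c(vocab$entries, nm_theta)
  out
}

# PseKNC features for a set; k may be a vector (per-k blocks concatenated).
pseknc_matrix <- function(set, k = 1:3, lam = 2L, w = 0.5,
                          properties = c("twist", "tilt", "roll",
                                         "shift", "slide", "rise")) {
  stopifnot(inherits(set, "labeled_seq_set"))
  blocks <- lapply(k, function(kk) {
    cfg <- pseknc_config(k = kk, lam = lam, w = w, properties = properties)
    vals <- t(vapply(set$records$sequence, pseknc2,
                     numeric(4^kk + lam * ncol(cfg$H)), config = cfg))
    colnames(vals) <- paste0("pseknc:k", kk, ":", colnames(vals))
    rownames(vals) <- set$records$id
    feature_matrix(vals, set$records$label,
                   method = rep("pseknc", ncol(vals)))
  })
  do.call(fm_cbind, blocks)
}
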