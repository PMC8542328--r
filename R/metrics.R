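#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Counts follow the origin-prediction convention: `n_pos` / `n_neg` are
#' the class sizes, `fn` the positives misjudged negative, `fp` the
#' negatives misjudged positive. The four metrics are
#' \deqn{Sn = 1 - FN/N^{+}, \quad Sp = 1 - FP/N^{-}, \quad
#'       Acc = 1 - (FN + FP)/(N^{+}+N^{-}),}
#' \deqn{MCC = \frac{1 - (FN/N^{+} + FP/N^{-})}
#'   {\sqrt{(1 + (FP-FN)/N^{+})(1 + (FN-FP)/N^{-})}}}
#' which is algebraically identical to the standard confusion-matrix MCC
#' \eqn{(TP\,TN - FP\,FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}} whenever
#' the denominator is nonzero. A zero denominator (every prediction the
#' same class) yields `mcc = 0` with `mcc_degenerate = TRUE`.
#'
#' @param n_pos,n_neg positive / negative class sizes (> 0).
#' @param fn false negatives, `0 <= fn <= n_pos`.
#' @param fp false positives, `0 <= fp <= n_neg`.
#' @return named list: `sn`, `sp`, `acc`, `mcc`, `mcc_degenerate`.
#' @export
compute_metrics <- function(n_pos, n_neg, fn, fp) {
  if (n_pos <= 0 || n_neg <= 0) stop("both classes must be non-empty")
  if (fn < 0 || fp < 0 || fn > n_pos || fp > n_neg)
    stop("error counts must satisfy 0 <= fn <= n_pos, 0 <= fp <= n_neg")
  sn <- 1 - fn / n_pos
  sp <- 1 - fp / n_neg
  acc <- 1 - (fn + fp) / (n_pos + n_neg)
  d1 <- 1 + (fp - fn) / n_pos
  d2 <- 1 + (fn - fp) / n_neg
  degenerate <- d1 <= 0 || d2 <= 0 || (d1 * d2) == 0
  # d1*d2 = (TP+FP)(TN+FN)/(N+ N-): zero iff no positive or no negative calls
  mcc <- if (degenerate) 0 else (1 - (fn / n_pos + fp / n_neg)) / sqrt(d1 * d2)
  list(sn = sn, sp = sp, acc = acc, mcc = mcc, mcc_degenerate = degenerate)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic with tie averaging, which
#' equals the trapezoidal area under the ROC built from thresholding the
#' scores: the probability a random positive outscores a random negative,
#' counting ties as 1/2.
#'
#' @param labels factor/character of `positive`/`negative`, or a logical
#'   vector marking positives.
#' @param scores numeric decision scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(labels, scores) {
  if (is.logical(labels)) pos <- labels
  else pos <- as.character(labels) == "positive"
  if (anyNA(pos) || any(!is.finite(scores)))
    stop("labels/scores contain missing or non-finite values")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
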