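#' Per-feature F-score
#'
#' The two-class F-score of feature i is the squared separation of the
#' class means from the grand mean, over the summed unbiased within-class
#' variances:
#' \deqn{F_i = \frac{(\bar{x}_i^{+} - \bar{x}_i)^2 +
#'                  (\bar{x}_i^{-} - \bar{x}_i)^2}
#'   {\frac{1}{n^{+}-1}\sum_k (x_{k,i}^{+} - \bar{x}_i^{+})^2 +
#'    \frac{1}{n^{-}-1}\sum_k (x_{k,i}^{-} - \bar{x}_i^{-})^2}}
#' Larger is more discriminative. If both within-class variances are zero
#' with a nonzero numerator (a perfectly separating constant), the
#' denominator is replaced by `eps = 1e-12`, yielding a large finite
#' score; if the numerator is also zero, F = 0.
#'
#' @param fm a [feature_matrix()] with >= 2 samples per class.
#' @param eps denominator floor for the degenerate zero-variance case.
#' @return object of class `feature_scores`: list with `names`, `score`,
#'   `method`, `rank` (descending-score permutation, ties stable by
#'   original column order).
#' @export
f_score <- function(fm, eps = 1e-12) {
  stopifnot(inherits(fm, "feature_matrix"))
  pos <- fm$labels == "positive"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos < 2 || n_neg < 2)
    stop("F-score needs at least 2 samples per class (variance undefined)")
  xp <- fm$x[pos, , drop = FALSE]
  xn <- fm$x[!pos, , drop = FALSE]
  mp <- colMeans(xp); mn <- colMeans(xn); m <- colMeans(fm$x)
  num <- (mp - m)^2 + (mn - m)^2
  den <- colSums((xp - rep(mp, each = n_pos))^2) / (n_pos - 1) +
         colSums((xn - rep(mn, each = n_neg))^2) / (n_neg - 1)
  score <- ifelse(den > 0, num / den, ifelse(num > 0, num / eps, 0))
  feature_scores(colnames(fm$x), score, "f_score")
}

feature_scores <- function(names, score, method) {
  if (any(!is.finite(score))) stop("non-finite feature score")
  structure(list(names = names, score = as.numeric(score), method = method,
                 rank = order(-score)),   # order() is stable: ties keep column order
            class = "feature_scores")
}

#' @export
print.feature_scores <- function(x, ...) {
  top <- x$names[x$rank[seq_len(min(5, length(x$rank)))]]
  cat(sprintf("feature_scores (%s): %d features; top: %s\n",
              x$method, length(x$score), paste(top, collapse = ", ")))
  invisible(x)
}

#' Rank features by F-score or by TF-IDF score
#'
#' The TF-IDF ranking orders TF-IDF-provenance columns by the fitted
#' model's per-tuple `tfidf` score (an unsupervised alternative to the
#' F-score that needs no labels at ranking time).
#'
#' @param fm a [feature_matrix()].
#' @param method `"f_score"` or `"tfidf_score"`.
#' @param tfidf_model required for `"tfidf_score"`: the fitted
#'   [fit_tfidf()] model whose columns `fm` contains.
#' @return a `feature_scores` object.
#' @export
rank_features <- function(fm, method = c("f_score", "tfidf_score"),
                          tfidf_model = NULL) {
  method <- match.arg(method)
  if (method == "f_score") return(f_score(fm))
  if (is.null(tfidf_model))
    stop("tfidf_score ranking requires a fitted tfidf_model")
  if (!all(fm$method == "tfidf"))
    stop("tfidf_score ranking requires TF-IDF-provenance columns only")
  tuples <- sub("^tfidf:", "", colnames(fm$x))
  missing <- setdiff(tuples, names(tfidf_model$tfidf))
  if (length(missing))
    stop("columns not in the TF-IDF model: ", paste(missing[1:min(3, length(missing))], collapse = ", "))
  feature_scores(colnames(fm$x), unname(tfidf_model$tfidf[tuples]),
                 "tfidf_score")
}

#' Incremental feature selection (IFS)
#'
#' Walks the ranked feature list from the top, evaluating nested subsets
#' top-1, top-(1+step), ... (always including the full `max_count`), and
#' returns the accuracy curve together with the subset size maximizing
#' cross-validated accuracy. Ties on the maximum go to the smallest
#' subset. The curve depends only on the ranking and the evaluator.
#'
#' @param fm a [feature_matrix()].
#' @param scores a `feature_scores` ranking over `fm`'s columns.
#' @param evaluator function(x, y) -> scalar CV accuracy for a column
#'   subset `x` with labels `y`; defaults to 5-fold cross-validated
#'   accuracy of an RBF-kernel SVM at default hyperparameters
#'   (see [cv_accuracy_evaluator()]).
#' @param max_count largest subset size to consider (default: all).
#' @param step stride through subset sizes (default 1, i.e. one by one).
#' @return object of class `selection_result`: `curve` (data.frame
#'   `feature_count`, `accuracy`), `best_count`, `selected` (names),
#'   `ranking` (the `feature_scores` used).
#' @export
incremental_feature_selection <- function(fm, scores, evaluator = NULL,
                                          max_count = NULL, step = 1L) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(scores, "feature_scores"))
  if (step < 1) stop("step must be >= 1")
  if (!identical(scores$names, colnames(fm$x)))
    stop("scores are not aligned to the feature matrix columns")
  if (is.null(evaluator)) evaluator <- cv_accuracy_evaluator()
  p <- ncol(fm$x)
  if (is.null(max_count)) max_count <- p
  max_count <- min(max_count, p)
  sizes <- unique(c(seq(1L, max_count, by = step), max_count))
  acc <- vapply(sizes, function(j) {
    sub <- fm$x[, scores$rank[seq_len(j)], drop = FALSE]
    a <- evaluator(sub, fm$labels)
    if (!is.finite(a))
      stop("evaluator returned a non-finite accuracy at subset size ", j)
    a
  }, numeric(1))
  best <- sizes[which.max(acc)]   # which.max takes the first max -> smallest count
  structure(
    list(curve = data.frame(feature_count = sizes, accuracy = acc),
         best_count = best,
         selected = scores$names[scores$rank[seq_len(best)]],
         ranking = scores),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: best_count = %d (accuracy %.4f) of %d evaluated sizes\n",
              x$best_count, max(x$curve$accuracy), nrow(x$curve)))
  invisible(x)
}

#' Default IFS evaluator: k-fold CV accuracy of a fixed classifier
#'
#' @param family classifier family (see [classifier_spec()]).
#' @param params hyperparameters passed to the classifier fit.
#' @param folds number of stratified CV folds.
#' @param seed seed for the fold assignment (fixed so IFS curves are
#'   reproducible).
#' @return function(x, y) -> mean CV accuracy.
#' @export
cv_accuracy_evaluator <- function(family = "svm", params = list(),
                                  folds = 5L, seed = 1L) {
  force(family); force(params); force(folds); force(seed)
  function(x, y) {
    fm <- feature_matrix(x, y, method = "subset")
    rep <- repeated_cv(family, params, fm, folds = folds, repeats = 1L,
                       seed = seed)
    rep$mean[["Acc"]]
  }
}

#' Serialize / load a selection result
#'
#' Writes the accuracy curve as a TSV (`feature_count`, `accuracy`) and
#' the selected feature names as a plain-text list.
#'
#' @param res a `selection_result`.
#' @param curve_path,selected_path output paths.
#' @return invisibly, the paths.
#' @export
write_selection_result <- function(res, curve_path, selected_path) {
  utils::write.table(res$curve, curve_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(res$selected, selected_path)
  invisible(c(curve_path, selected_path))
}
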