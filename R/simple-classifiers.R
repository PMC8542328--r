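# Gaussian naive Bayes and k-nearest neighbours. Naive Bayes is written
# in-package (no NB package in the target environment); k-NN wraps the
# FNN package's exact neighbour search.

fit_naive_bayes <- function(x, y, var_smoothing = 1e-9, seed = 1L) {
  x <- as.matrix(x)
  pos <- y == "positive"
  stat <- function(m) {
    v <- apply(m, 2, stats::var)
    v[!is.finite(v)] <- 0
    list(mu = colMeans(m), var = v)
  }
  sp <- stat(x[pos, , drop = FALSE])
  sn <- stat(x[!pos, , drop = FALSE])
  # floor variances at var_smoothing * largest feature variance (sklearn rule)
  floor_ <- var_smoothing * max(apply(x, 2, stats::var), 1e-30)
  sp$var <- pmax(sp$var, floor_); sn$var <- pmax(sn$var, floor_)
  structure(list(pos = sp, neg = sn,
                 log_prior = log(mean(pos)) - log(mean(!pos))),
            class = c("oriclass_nb", "oriclass_fit"))
}

nb_loglik <- function(stat, x) {
  rowSums(sweep(-(sweep(x, 2, stat$mu, `-`)^2), 2, 2 * stat$var, `/`) -
            matrix(0.5 * log(2 * pi * stat$var), nrow(x), ncol(x), byrow = TRUE))
}

#' @export
predict_scores.oriclass_nb <- function(fit, x) {
  x <- as.matrix(x)
  nb_loglik(fit$pos, x) - nb_loglik(fit$neg, x) + fit$log_prior
}

fit_knn <- function(x, y, k = 5L, seed = 1L) {
  structure(list(X = as.matrix(x), y = y == "positive", k = as.integer(k)),
            class = c("oriclass_knn", "oriclass_fit"))
}

#' @export
predict_scores.oriclass_knn <- function(fit, x) {
  k <- min(fit$k, nrow(fit$X))
  nn <- FNN::get.knnx(fit$X, as.matrix(x), k = k)$nn.index
  votes <- matrix(fit$y[nn], nrow = nrow(nn))
  rowMeans(votes) - 0.5              # fraction of positive neighbours, centred
}
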