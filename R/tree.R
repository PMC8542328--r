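# CART-style binary tree grown by variance reduction. For a 0/1 response
# variance reduction selects the same splits as the Gini criterion
# (impurity 2p(1-p) vs variance p(1-p)), so one grower serves both the
# classification tree and the regression trees inside gradient boosting.
# Leaves store sum(resp) and sum(hess): with hess = 1 the leaf value is
# the response mean; gradient boosting passes Newton hessians instead.

tree_best_split <- function(X, resp, idx, min_leaf = 1L) {
  n <- length(idx)
  best <- list(gain = 0)
  s_tot <- sum(resp[idx])
  for (j in seq_len(ncol(X))) {
    xv <- X[idx, j]
    ord <- order(xv)
    xs <- xv[ord]; rs <- resp[idx][ord]
    cs <- cumsum(rs)
    # candidate split after position i: left = 1..i
    i <- seq_len(n - 1)
    valid <- xs[i] < xs[i + 1] & i >= min_leaf & (n - i) >= min_leaf
    if (!any(valid)) next
    nl <- i[valid]; sl <- cs[nl]
    # SSE reduction = s_l^2/n_l + s_r^2/n_r - s_tot^2/n  (ss terms cancel)
    gain <- sl^2 / nl + (s_tot - sl)^2 / (n - nl) - s_tot^2 / n
    m <- which.max(gain)
    if (gain[m] > best$gain + 1e-12) {
      pos <- nl[m]
      best <- list(gain = gain[m], feature = j,
                   threshold = (xs[pos] + xs[pos + 1]) / 2)
    }
  }
  if (is.null(best$feature)) NULL else best
}

grow_tree <- function(X, resp, hess = NULL, idx = seq_len(nrow(X)),
                      depth = 0L, max_depth = 10L, min_split = 2L) {
  n <- length(idx)
  if (is.null(hess)) hess <- rep(1, nrow(X))
  leaf <- function() {
    h <- sum(hess[idx])
    list(leaf = TRUE, value = if (h > 0) sum(resp[idx]) / h else 0, n = n)
  }
  if (depth >= max_depth || n < min_split || n < 2) return(leaf())
  sp <- tree_best_split(X, resp, idx)
  if (is.null(sp)) return(leaf())
  go_left <- X[idx, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_tree(X, resp, hess, idx[go_left], depth + 1L,
                        max_depth, min_split),
       right = grow_tree(X, resp, hess, idx[!go_left], depth + 1L,
                         max_depth, min_split))
}

predict_tree <- function(node, X) {
  out <- numeric(nrow(X))
  recurse <- function(node, rows) {
    if (length(rows) == 0) return()
    if (node$leaf) { out[rows] <<- node$value; return() }
    left <- X[rows, node$feature] <= node$threshold
    recurse(node$left, rows[left])
    recurse(node$right, rows[!left])
  }
  recurse(node, seq_len(nrow(X)))
  out
}

fit_decision_tree <- function(x, y, min_split = 2L, max_depth = 10L,
                              seed = 1L) {
  x <- as.matrix(x)
  yb <- as.numeric(y == "positive")
  tree <- grow_tree(x, yb, max_depth = as.integer(max_depth),
                    min_split = as.integer(min_split))
  structure(list(tree = tree),
            class = c("oriclass_tree", "oriclass_fit"))
}

#' @export
predict_scores.oriclass_tree <- function(fit, x) {
  # leaf positive-class probability, centred so score > 0 <=> positive
  predict_tree(fit$tree, as.matrix(x)) - 0.5
}

# Gradient boosted trees with logistic loss and Newton leaf values
# (second-order, xgboost-style): at each round fit a depth-limited tree
# to the gradient residual y - p with hessian p(1 - p).
fit_gbt <- function(x, y, n_estimators = 100L, learning_rate = 0.1,
                    max_depth = 3L, min_split = 2L, seed = 1L) {
  x <- as.matrix(x)
  yb <- as.numeric(y == "positive")
  p0 <- min(max(mean(yb), 1e-10), 1 - 1e-10)
  f0 <- log(p0 / (1 - p0))
  f <- rep(f0, nrow(x))
  trees <- vector("list", n_estimators)
  for (m in seq_len(n_estimators)) {
    p <- stats::plogis(f)
    trees[[m]] <- grow_tree(x, yb - p, hess = p * (1 - p),
                            max_depth = as.integer(max_depth),
                            min_split = as.integer(min_split))
    f <- f + learning_rate * predict_tree(trees[[m]], x)
  }
  structure(list(f0 = f0, trees = trees, learning_rate = learning_rate),
            class = c("oriclass_gbt", "oriclass_fit"))
}

#' @export
predict_scores.oriclass_gbt <- function(fit, x) {
  x <- as.matrix(x)
  f <- rep(fit$f0, nrow(x))
  for (tr in fit$trees) f <- f + fit$learning_rate * predict_tree(tr, x)
  f                                  # logit score
}
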