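# RBF-kernel support-vector classifier with squared-hinge (L2) loss,
# optimized by L-BFGS in the representer form f(x) = sum_i a_i K(x_i, x) + b:
#   min_a,b  0.5 a' K a + C * sum_i max(0, 1 - y_i f(x_i))^2
# The squared hinge makes the objective differentiable, so a quasi-Newton
# solver converges quickly at the few-hundred-sample scale this package
# targets. Written in-package because no SVM package is available in the
# target environment.

rbf_kernel <- function(a, b, gamma) {
  # ||u - v||^2 = ||u||^2 + ||v||^2 - 2 u.v, computed blockwise
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

fit_svm <- function(x, y, cost = 1, gamma = NULL, maxit = 200L, seed = 1L) {
  x <- as.matrix(x)
  sc <- fit_scaler(x)
  X <- apply_scaler(sc, x)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  yy <- ifelse(y == "positive", 1, -1)
  K <- rbf_kernel(X, X, gamma)
  n <- nrow(X)
  obj <- function(theta) {
    a <- theta[seq_len(n)]; b <- theta[n + 1]
    f <- as.vector(K %*% a) + b
    h <- pmax(0, 1 - yy * f)
    0.5 * sum(a * (K %*% a)) + cost * sum(h^2)
  }
  grad <- function(theta) {
    a <- theta[seq_len(n)]; b <- theta[n + 1]
    Ka <- as.vector(K %*% a)
    h <- pmax(0, 1 - yy * (Ka + b))
    gf <- -2 * cost * yy * h
    c(Ka + as.vector(K %*% gf), sum(gf))
  }
  opt <- stats::optim(numeric(n + 1), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  structure(list(alpha = opt$par[seq_len(n)], b = opt$par[n + 1],
                 X = X, gamma = gamma, cost = cost, scaler = sc,
                 converged = opt$convergence == 0),
            class = c("oriclass_svm", "oriclass_fit"))
}

#' @export
predict_scores.oriclass_svm <- function(fit, x) {
  Xnew <- apply_scaler(fit$scaler, as.matrix(x))
  K <- rbf_kernel(Xnew, fit$X, fit$gamma)
  as.vector(K %*% fit$alpha) + fit$b
}
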