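# Single-hidden-layer multi-layer perceptron, trained full-batch by
# L-BFGS on the L2-penalized cross-entropy. This mirrors the common
# scientific-python configuration: one hidden layer (default 100 units),
# rectifier activation, logistic output, penalty alpha * ||W||^2 / (2n).
# Written in-package because no neural-network package is available in
# the target environment.

mlp_init <- function(d, hidden, seed) {
  set.seed(seed)
  # Glorot-uniform initialization
  r1 <- sqrt(6 / (d + hidden))
  r2 <- sqrt(6 / (hidden + 1))
  list(W1 = matrix(stats::runif(d * hidden, -r1, r1), d, hidden),
       b1 = numeric(hidden),
       W2 = stats::runif(hidden, -r2, r2),
       b2 = 0)
}

mlp_pack <- function(p) c(as.vector(p$W1), p$b1, p$W2, p$b2)

mlp_unpack <- function(theta, d, hidden) {
  i <- d * hidden
  list(W1 = matrix(theta[seq_len(i)], d, hidden),
       b1 = theta[i + seq_len(hidden)],
       W2 = theta[i + hidden + seq_len(hidden)],
       b2 = theta[i + 2 * hidden + 1])
}

# Numerically stable binary cross-entropy from logits:
# CE(z, y) = max(z,0) - z y + log(1 + exp(-|z|))
mlp_objective <- function(theta, X, y, alpha, d, hidden) {
  p <- mlp_unpack(theta, d, hidden)
  n <- nrow(X)
  z1 <- sweep(X %*% p$W1, 2, p$b1, `+`)
  a1 <- pmax(z1, 0)
  z2 <- as.vector(a1 %*% p$W2) + p$b2
  ce <- mean(pmax(z2, 0) - z2 * y + log1p(exp(-abs(z2))))
  ce + alpha / (2 * n) * (sum(p$W1^2) + sum(p$W2^2))
}

mlp_gradient <- function(theta, X, y, alpha, d, hidden) {
  p <- mlp_unpack(theta, d, hidden)
  n <- nrow(X)
  z1 <- sweep(X %*% p$W1, 2, p$b1, `+`)
  a1 <- pmax(z1, 0)
  z2 <- as.vector(a1 %*% p$W2) + p$b2
  prob <- stats::plogis(z2)
  dz2 <- (prob - y) / n
  gW2 <- as.vector(crossprod(a1, dz2)) + alpha / n * p$W2
  gb2 <- sum(dz2)
  dz1 <- (dz2 %o% p$W2) * (z1 > 0)
  gW1 <- crossprod(X, dz1) + alpha / n * p$W1
  gb1 <- colSums(dz1)
  c(as.vector(gW1), gb1, gW2, gb2)
}

fit_mlp <- function(x, y, hidden = 100L, alpha = 1e-4, maxit = 200L,
                    seed = 1L) {
  x <- as.matrix(x)
  sc <- fit_scaler(x)
  X <- apply_scaler(sc, x)
  yb <- as.numeric(y == "positive")
  d <- ncol(X)
  theta0 <- mlp_pack(mlp_init(d, hidden, seed))
  opt <- stats::optim(theta0, mlp_objective, mlp_gradient,
                      X = X, y = yb, alpha = alpha, d = d, hidden = hidden,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit))
  structure(list(theta = opt$par, d = d, hidden = hidden, scaler = sc,
                 alpha = alpha, converged = opt$convergence == 0),
            class = c("oriclass_mlp", "oriclass_fit"))
}

#' @export
predict_scores.oriclass_mlp <- function(fit, x) {
  X <- apply_scaler(fit$scaler, as.matrix(x))
  p <- mlp_unpack(fit$theta, fit$d, fit$hidden)
  a1 <- pmax(sweep(X %*% p$W1, 2, p$b1, `+`), 0)
  as.vector(a1 %*% p$W2) + p$b2     # logit score; > 0 <=> positive call
}

# Column-wise standardization shared by the margin-based classifiers.
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1
  list(mu = mu, sd = sd_)
}

apply_scaler <- function(sc, x) {
  sweep(sweep(x, 2, sc$mu, `-`), 2, sc$sd, `/`)
}
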