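# shared fixtures and independent oracles

# multivariate normal draws, independent of the package internals
draw_mvn <- function(n, mu, Sigma, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(mu)), n, length(mu)) %*% chol(Sigma)
  sweep(X, 2, mu, "+")
}

a09_matrix <- function(d) outer(1:d, 1:d, function(j, k) (-0.9)^abs(j - k))

# standard normal upper tail by numerical integration (oracle for pnorm)
norm_upper_tail_oracle <- function(z) {
  stats::integrate(function(x) exp(-x^2 / 2) / sqrt(2 * pi), z, Inf,
                   rel.tol = 1e-12)$value
}

# chi-square upper tail by numerical integration (oracle for pchisq)
chisq_upper_tail_oracle <- function(x, df) {
  stats::integrate(function(t) t^(df / 2 - 1) * exp(-t / 2) /
                     (2^(df / 2) * gamma(df / 2)),
                   x, Inf, rel.tol = 1e-12)$value
}

# brute-force AUC over all positive-negative pairs
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# small z-matrix tibble with known gene names
tiny_z <- function(values, genes = NULL) {
  values <- as.matrix(values)
  rownames(values) <- genes %||% paste0("gene", seq_len(nrow(values)))
  as_zmatrix(values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 200 x 3 screen fixture with 10 planted row outliers far outside the
# 99.99% Mahalanobis surface of the generating covariance
screen_fixture <- function(seed = 42) {
  Sigma <- matrix(c(1, 0.4, 0.2, 0.4, 1, 0.4, 0.2, 0.4, 1), 3)
  X <- draw_mvn(200, rep(0, 3), Sigma, seed)
  e <- eigen(Sigma, symmetric = TRUE)
  u <- e$vectors[, 3] * sqrt(e$values[3])
  out_rows <- 1:10
  signs <- rep(c(-1, 1), length.out = 10)
  X[out_rows, ] <- (signs * sqrt(qchisq(0.9999, 3))) %o% u
  rownames(X) <- sprintf("G%03d", 1:200)
  list(z = as_zmatrix(X), outliers = rownames(X)[out_rows])
}
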