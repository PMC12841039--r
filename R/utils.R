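# internal helpers shared across modules

# smallest p-value reported or passed to log(); preserves ranking while
# keeping -2*log(p) finite
P_FLOOR <- 1e-300

floor_p <- function(p) pmin(pmax(p, P_FLOOR), 1)

# deterministic small-integer hash for seed derivation (< 2^31 - 1);
# a polynomial string hash so replicate streams are reproducible without
# external dependencies
stable_seed <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = "|")
  h <- 17
  for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 2147483629
  as.integer(h)
}

# run `expr` under a given seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# symmetrize and clip eigenvalues below rel * largest; guards block inversions
clip_pd <- function(S, rel = 1e-6) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, rel * max(e$values))
  S2 <- e$vectors %*% (v * t(e$vectors))
  dimnames(S2) <- dimnames(S)
  (S2 + t(S2)) / 2
}

# draw n rows from N(mu, Sigma) (upper-triangular Cholesky)
rmvnorm_chol <- function(n, mu, Sigma) {
  d <- length(mu)
  X <- matrix(stats::rnorm(n * d), n, d) %*% chol(Sigma)
  sweep(X, 2, mu, "+")
}

zstop <- function(msg, class = "zscreen_error") abort(msg, class = class)
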