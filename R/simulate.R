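#' Covariance structures for the simulation design
#'
#' Three correlation structures for simulated z-statistic columns:
#' `"independent"` is the identity; `"A09"` has entries
#' `sigma_jk = (-0.9)^|j - k|` (strong alternating serial correlation);
#' `"ALYZ"` is a random correlation matrix with condition number 100, built
#' by drawing a random orthogonal basis (QR of a seeded standard-normal
#' matrix), spreading the eigenvalues geometrically to a 100-fold range,
#' rescaling to unit diagonal, and iterating the re-spread/re-normalize pair
#' until the condition number is within 1 of 100 (at most 50 iterations).
#'
#' @param correlation One of `"independent"`, `"ALYZ"`, `"A09"`.
#' @param d Dimension (number of phenotype columns), at least 2.
#' @param seed Seed for the ALYZ draw (ignored by the other kinds).
#' @return A d x d covariance matrix; deterministic given `correlation`,
#'   `d` and `seed`.
#' @examples
#' make_sigma("A09", 3)
#' @export
make_sigma <- function(correlation = c("independent", "ALYZ", "A09"), d,
                       seed = 1) {
  correlation <- match.arg(correlation)
  if (d < 2) zstop("d must be at least 2")
  switch(correlation,
    independent = diag(d),
    A09 = outer(seq_len(d), seq_len(d), function(j, k) (-0.9)^abs(j - k)),
    ALYZ = with_seed(seed, alyz_sigma(d)))
}

# random correlation matrix with condition number 100 (+/- 1)
alyz_sigma <- function(d, target = 100, tol = 1, max_iter = 50L) {
  Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  lam <- target^(-(seq_len(d) - 1) / (d - 1))  # geometric, ratio = target
  R <- Q %*% (lam * t(Q))
  for (i in seq_len(max_iter)) {
    R <- stats::cov2cor(R)
    e <- eigen(R, symmetric = TRUE)
    cond <- max(e$values) / min(e$values)
    if (abs(cond - target) <= tol) break
    # re-spread eigenvalues on the log scale to span exactly log(target)
    lv <- log(e$values)
    lv <- (lv - min(lv)) / (max(lv) - min(lv)) * log(target)
    R <- e$vectors %*% (exp(lv) * t(e$vectors))
  }
  (R + t(R)) / 2
}

#' Simulate a contaminated multivariate-normal z-statistic dataset
#'
#' Clean rows are drawn from N(0, Sigma) with Sigma chosen by
#' [make_sigma()]. Contamination follows one of three mechanisms:
#'
#' * `"rows"`: `floor(perout * n)` randomly chosen rows are replaced by
#'   `s * (1 + gamma) * sqrt(qchisq(0.99, d)) * u`, where `u` is the
#'   smallest-eigenvalue eigenvector of Sigma scaled to unit Mahalanobis
#'   norm (`u' Sigma^{-1} u = 1`) and `s` is a random sign per row. Each
#'   replaced row thus sits at squared Mahalanobis distance
#'   `(1 + gamma)^2 * qchisq(0.99, d)` exactly — `gamma` of the way beyond
#'   the 99% reference surface — in the direction least favored by the
#'   covariance.
#' * `"entries"`: each cell is independently replaced with probability
#'   `perout` by `s * (1 + gamma) * sqrt(qchisq(0.99, 1)) * sqrt(Sigma_jj)`,
#'   i.e. `gamma` of the way beyond the marginal 99% band.
#' * `"both"`: half the budget to each — `floor(perout * n / 2)` replaced
#'   rows, and entry contamination with probability `perout / 2` on the
#'   remaining rows.
#'
#' `gamma` is the fractional exceedance of the 99% reference surface:
#' contaminated values sit outside the boundary that a calibrated method
#' would draw, by 25% (`gamma = 0.25`) or 50% (`gamma = 0.5`) of its
#' radius. Sub-streams for structure, the clean draw, and each contamination step
#' are derived deterministically from `seed`, so changing the mechanism does
#' not perturb the clean draw.
#'
#' @param d Dimension (columns).
#' @param n Number of rows.
#' @param correlation Correlation structure, see [make_sigma()].
#' @param mechanism One of `"rows"`, `"entries"`, `"both"`.
#' @param perout Contamination fraction in (0, 0.5).
#' @param gamma Outlier magnitude: fractional exceedance of the 99%
#'   reference surface.
#' @param seed Integer root seed; identical seed and setting give
#'   bit-identical datasets.
#' @return An object of class `sim_dataset`: list with `values` (z-matrix
#'   tibble, genes `g0001`, ...), `sigma_true`, `row_labels` (1 = replaced
#'   row or row containing >= 1 contaminated cell), `cell_labels` (n x d
#'   0/1 matrix), `replaced_rows` (0/1 vector) and `setting`.
#' @examples
#' sim <- simulate_dataset(d = 5, n = 200, correlation = "A09",
#'                         mechanism = "rows", perout = 0.05, gamma = 0.5)
#' sum(sim$row_labels)
#' @export
simulate_dataset <- function(d = 5, n = 1000,
                             correlation = c("independent", "ALYZ", "A09"),
                             mechanism = c("rows", "entries", "both"),
                             perout = 0.01, gamma = 0.25, seed = 1) {
  correlation <- match.arg(correlation)
  mechanism <- match.arg(mechanism)
  if (perout <= 0 || perout >= 0.5) zstop("perout must be in (0, 0.5)")
  Sigma <- make_sigma(correlation, d, seed = stable_seed(seed, "structure"))
  X <- with_seed(stable_seed(seed, "clean"),
                 rmvnorm_chol(n, rep(0, d), Sigma))
  cell_labels <- matrix(0L, n, d)
  replaced <- integer(n)

  row_budget <- switch(mechanism, rows = floor(perout * n),
                       entries = 0L, both = floor(perout * n / 2))
  cell_prob <- switch(mechanism, rows = 0, entries = perout,
                      both = perout / 2)

  if (row_budget > 0L) {
    e <- eigen(Sigma, symmetric = TRUE)
    v <- e$vectors[, d]                      # smallest-eigenvalue direction
    u <- v * sqrt(e$values[d])               # unit Mahalanobis norm
    with_seed(stable_seed(seed, "rows"), {
      idx <- sample.int(n, row_budget)
      s <- sample(c(-1, 1), row_budget, replace = TRUE)
      X[idx, ] <- (s * (1 + gamma) * sqrt(stats::qchisq(0.99, d))) %o% u
      replaced[idx] <- 1L
    })
  }
  if (cell_prob > 0) {
    with_seed(stable_seed(seed, "entries"), {
      eligible <- which(replaced == 0L)
      mask <- matrix(stats::runif(length(eligible) * d) < cell_prob,
                     length(eligible), d)
      signs <- matrix(sample(c(-1, 1), length(eligible) * d, replace = TRUE),
                      length(eligible), d)
      val <- sweep(signs * (1 + gamma) * sqrt(stats::qchisq(0.99, 1)), 2,
                   sqrt(diag(Sigma)), "*")
      Xe <- X[eligible, , drop = FALSE]
      Xe[mask] <- val[mask]
      X[eligible, ] <- Xe
      cell_labels[eligible, ] <- mask * 1L
    })
  }
  genes <- sprintf("g%04d", seq_len(n))
  colnames(X) <- sprintf("p%d", seq_len(d))
  rownames(X) <- genes
  structure(list(
    values = as_zmatrix(X), sigma_true = Sigma,
    row_labels = as.integer(replaced | rowSums(cell_labels) > 0),
    cell_labels = cell_labels, replaced_rows = replaced,
    setting = list(d = d, n = n, correlation = correlation,
                   mechanism = mechanism, perout = perout, gamma = gamma,
                   seed = seed)),
    class = "sim_dataset")
}

#' Simulate the clean bivariate calibration dataset
#'
#' `n` points from a bivariate normal distribution with mean (0, 0), unit
#' standard deviations and correlation `rho`; no contamination, all labels
#' zero.
#'
#' @param n Number of points.
#' @param rho Correlation between the two columns.
#' @param seed Integer seed.
#' @return A `sim_dataset` (see [simulate_dataset()]) with d = 2.
#' @export
simulate_fig1 <- function(n = 10000, rho = 0.5, seed = 1) {
  Sigma <- matrix(c(1, rho, rho, 1), 2)
  X <- with_seed(stable_seed(seed, "fig1"),
                 rmvnorm_chol(n, c(0, 0), Sigma))
  colnames(X) <- c("p1", "p2")
  rownames(X) <- sprintf("g%05d", seq_len(n))
  structure(list(
    values = as_zmatrix(X), sigma_true = Sigma,
    row_labels = integer(n), cell_labels = matrix(0L, n, 2),
    replaced_rows = integer(n),
    setting = list(d = 2, n = n, correlation = "bivariate", rho = rho,
                   mechanism = "none", perout = 0, gamma = 0, seed = seed)),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  s <- x$setting
  cat("simulated z-matrix: ", s$n, " x ", s$d, " (", s$correlation,
      ", mechanism ", s$mechanism, ", perout ", s$perout, ", gamma ",
      s$gamma, ", seed ", s$seed, ")\n", sep = "")
  cat("  outlier rows: ", sum(x$row_labels), "\n", sep = "")
  invisible(x)
}

#' Tidy a simulated dataset into one row per gene
#'
#' @param x A `sim_dataset` object.
#' @param ... Unused.
#' @return The `values` tibble with an appended `row_outlier` label column.
#' @export
tidy.sim_dataset <- function(x, ...) {
  dplyr::mutate(x$values, row_outlier = x$row_labels)
}

#' The full 72-setting simulation grid
#'
#' All combinations of dimension (5, 10), contamination fraction
#' (0.01, 0.05), outlier magnitude (0.25, 0.5), mechanism (rows, entries,
#' both) and correlation structure (independent, ALYZ, A09).
#'
#' @param n Rows per simulated dataset (default 1000).
#' @return A tibble with 72 rows and columns `d`, `n`, `perout`, `gamma`,
#'   `mechanism`, `correlation`.
#' @export
simulation_grid <- function(n = 1000) {
  tidyr::expand_grid(
    d = c(5L, 10L), perout = c(0.01, 0.05), gamma = c(0.25, 0.5),
    mechanism = c("rows", "entries", "both"),
    correlation = c("independent", "ALYZ", "A09")) |>
    dplyr::mutate(n = n, .after = "d")
}
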