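#' Robust center and covariance by cellwise minimum covariance determinant
#'
#' Estimates the multivariate location and scatter of the rows of a
#' z-statistic matrix while flagging individual cells (gene-phenotype
#' entries) that are inconsistent with the bulk of the data. The estimator
#' minimizes a missing-data Gaussian likelihood criterion
#'
#'   `sum_g [-log phi(z_{g,O_g}; mu_{O_g}, Sigma_{O_g,O_g})] + q * #flags`,
#'
#' where `O_g` is the set of unflagged cells in row g and `q` (`penalty_q`)
#' is the price of flagging one cell, by alternating two steps:
#'
#' * W-step: for every cell, the conditional mean and SD given the row's
#'   other unflagged cells are computed; a cell's flag is toggled when doing
#'   so lowers the objective (flag when the cell's negative conditional
#'   log-density `0.5*log(2*pi*c) + 0.5*r^2` exceeds `q`). One toggle per
#'   row per sweep keeps every accepted change an exact objective decrease;
#'   sweeps repeat until no toggle helps. A per-column budget keeps at least
#'   `ceiling(alpha * m)` cells unflagged in every column (flags beyond the
#'   budget are released smallest-residual-first).
#' * Estimation step: one EM update treating flagged cells as missing —
#'   flagged cells are imputed by their conditional expectation and the
#'   covariance update adds each row's conditional covariance of its flagged
#'   block.
#'
#' Initialization is deterministic: columnwise median center, initial flags
#' at 3 robust SDs (median/MAD), and an initial scatter built from
#' Gaussian-rank correlations scaled by MAD-based SDs. After convergence,
#' when at least one cell was flagged, the covariance is rescaled by the
#' consistency factor `median(h_g) / qchisq(0.5, d)` (as is standard for MCD
#' estimators) so that the squared Mahalanobis distances of clean rows match
#' their chi-square reference; with no flags the estimate already is the
#' maximum-likelihood one and no factor is applied.
#'
#' @param z A z-matrix (data frame or matrix, see [as_zmatrix()]) with at
#'   least `5 * d` rows.
#' @param alpha Minimum unflagged fraction per column, in (0.5, 1].
#' @param penalty_q Per-cell flag penalty on the squared-residual scale;
#'   default `qchisq(0.99, 1)` (about 6.6349), i.e. a residual cutoff of
#'   2.5758 ("2.57").
#' @param max_iter Maximum number of alternating iterations.
#' @param tol Relative objective-change convergence tolerance.
#' @return An object of class `cellmcd_fit`: a list with elements `center`
#'   (named length-d vector), `covariance` (d x d positive-definite matrix),
#'   `flags` (m x d matrix, 1 = unflagged), `predictions`, `cond_sd` and
#'   `residuals` (m x d matrices; `residuals = (z - predictions)/cond_sd`),
#'   `objective_trace`, `iterations`, `converged`, `n_flagged`,
#'   `consistency_factor`, `genes`, `phenotypes`, and the parameters used.
#' @seealso [cellmcd_rank()], [flag_entries()], [cell_predict()]
#' @examples
#' set.seed(1)
#' fit <- fit_cellmcd(matrix(rnorm(300), 100, 3))
#' glance(fit)
#' @export
fit_cellmcd <- function(z, alpha = 0.75, penalty_q = stats::qchisq(0.99, 1),
                        max_iter = 100L, tol = 1e-6) {
  z <- as_zmatrix(z)
  X <- zmat_values(z)
  m <- nrow(X); d <- ncol(X)
  if (alpha <= 0.5 || alpha > 1) zstop("alpha must be in (0.5, 1]")
  if (m < 5 * d)
    zstop(paste0("need at least 5*d = ", 5 * d, " rows to estimate a ", d,
                 "x", d, " covariance robustly; got ", m,
                 " (supply more genes or fewer phenotypes)"))
  sds <- apply(X, 2, stats::sd)
  if (any(!is.finite(sds) | sds <= 0))
    zstop(paste0("constant phenotype column: ",
                 colnames(X)[which(sds <= 0)[1]]))

  init <- cellmcd_init(X)
  mu <- init$mu; Sigma <- init$Sigma; W <- init$W
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W <- cellmcd_wstep(X, mu, Sigma, W, penalty_q, alpha)
    es <- cellmcd_estep(X, mu, Sigma, W)
    mu <- es$mu
    Sigma <- clip_pd(es$Sigma, 1e-6)
    obj <- cellmcd_objective(X, mu, Sigma, W, penalty_q)
    trace <- c(trace, obj)
    if (it > 1L &&
        abs(trace[it - 1L] - obj) < tol * (abs(trace[it - 1L]) + 1e-10)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warn(paste0("cellMCD did not converge in ", max_iter,
                " iterations; returning best iterate"))

  n_flagged <- sum(!W)
  cfac <- 1
  if (n_flagged > 0L) {
    h <- stats::mahalanobis(X, mu, Sigma)
    cfac <- stats::median(h) / stats::qchisq(0.5, d)
    Sigma <- Sigma * cfac
  }
  st <- loo_cell_stats(X, mu, Sigma, W)
  names(mu) <- colnames(X)
  structure(list(
    center = mu, covariance = Sigma,
    flags = matrix(as.integer(W), m, d, dimnames = dimnames(X)),
    predictions = st$pred, cond_sd = sqrt(st$cvar), residuals = st$resid,
    objective_trace = trace, iterations = length(trace),
    converged = converged, n_flagged = n_flagged,
    consistency_factor = cfac,
    genes = z$gene, phenotypes = zmat_phenotypes(z),
    alpha = alpha, penalty_q = penalty_q,
    residual_cutoff = sqrt(penalty_q)),
    class = "cellmcd_fit")
}

# deterministic robust initialization
cellmcd_init <- function(X) {
  m <- nrow(X)
  med <- apply(X, 2, stats::median)
  madv <- apply(X, 2, stats::mad)       # 1.4826 * MAD
  madv[madv <= 0] <- apply(X, 2, stats::sd)[madv <= 0]
  S0 <- sweep(sweep(X, 2, med), 2, madv, "/")
  W <- abs(S0) <= 3
  ns <- apply(X, 2, function(x) stats::qnorm((rank(x) - 0.5) / m))
  R <- stats::cor(ns)                   # Gaussian-rank correlation
  Sigma <- clip_pd(diag(madv, ncol(X)) %*% R %*% diag(madv, ncol(X)), 1e-4)
  dimnames(Sigma) <- list(colnames(X), colnames(X))
  list(mu = med, Sigma = Sigma, W = W)
}

pattern_key <- function(W) as.vector(W %*% 2^(seq_len(ncol(W)) - 1))

# conditional prediction, variance and standardized residual of every cell
# given the row's other unflagged cells; rows grouped by flag pattern so the
# per-pattern linear algebra is done once
loo_cell_stats <- function(X, mu, Sigma, W) {
  m <- nrow(X); d <- ncol(X)
  pred <- matrix(NA_real_, m, d, dimnames = dimnames(X))
  cvar <- matrix(NA_real_, m, d, dimnames = dimnames(X))
  Xc <- sweep(X, 2, mu)
  key <- pattern_key(W)
  for (k in unique(key)) {
    I <- which(key == k)
    O <- which(W[I[1L], ])
    M <- setdiff(seq_len(d), O)
    nI <- length(I)
    if (length(O) == 0L) {              # fully flagged row: marginal fallback
      pred[I, ] <- matrix(mu, nI, d, byrow = TRUE)
      cvar[I, ] <- matrix(diag(Sigma), nI, d, byrow = TRUE)
      next
    }
    K <- chol2inv(chol(Sigma[O, O, drop = FALSE]))
    if (length(O) == 1L) {              # lone kept cell: marginal
      pred[I, O] <- mu[O]
      cvar[I, O] <- Sigma[O, O]
    } else {
      kd <- diag(K)
      A <- Xc[I, O, drop = FALSE] %*% K
      pred[I, O] <- X[I, O, drop = FALSE] - sweep(A, 2, kd, "/")
      cvar[I, O] <- matrix(1 / kd, nI, length(O), byrow = TRUE)
    }
    if (length(M) > 0L) {
      B <- Sigma[M, O, drop = FALSE] %*% K
      pred[I, M] <- matrix(mu[M], nI, length(M), byrow = TRUE) +
        Xc[I, O, drop = FALSE] %*% t(B)
      cv <- diag(Sigma)[M] - rowSums(B * Sigma[M, O, drop = FALSE])
      cvar[I, M] <- matrix(pmax(cv, 1e-12), nI, length(M), byrow = TRUE)
    }
  }
  list(pred = pred, cvar = cvar, resid = (X - pred) / sqrt(cvar))
}

# toggle flags toward lower objective; one exact toggle per row per sweep
cellmcd_wstep <- function(X, mu, Sigma, W, q, alpha) {
  m <- nrow(X); d <- ncol(X)
  for (swp in seq_len(d + 3L)) {
    st <- loo_cell_stats(X, mu, Sigma, W)
    cost <- 0.5 * log(2 * pi * st$cvar) + 0.5 * st$resid^2
    gain <- ifelse(W, cost - q, q - cost)   # objective drop if toggled
    best <- max.col(gain, ties.method = "first")
    hit <- which(gain[cbind(seq_len(m), best)] > 1e-12)
    if (length(hit) == 0L) break
    idx <- cbind(hit, best[hit])
    W[idx] <- !W[idx]
  }
  # per-column flag budget: keep >= ceiling(alpha * m) cells per column
  max_flags <- m - ceiling(alpha * m)
  if (any(colSums(!W) > max_flags)) {
    st <- loo_cell_stats(X, mu, Sigma, W)
    for (j in seq_len(d)) {
      excess <- sum(!W[, j]) - max_flags
      if (excess > 0L) {
        fl <- which(!W[, j])
        W[fl[order(st$resid[fl, j]^2)][seq_len(excess)], j] <- TRUE
      }
    }
  }
  W
}

# one EM update of (mu, Sigma) treating flagged cells as missing
cellmcd_estep <- function(X, mu, Sigma, W) {
  m <- nrow(X); d <- ncol(X)
  Ximp <- X
  Cacc <- matrix(0, d, d)
  Xc <- sweep(X, 2, mu)
  key <- pattern_key(W)
  for (k in unique(key)) {
    I <- which(key == k)
    O <- which(W[I[1L], ]); M <- setdiff(seq_len(d), O)
    if (length(M) == 0L) next
    if (length(O) == 0L) {
      Ximp[I, ] <- matrix(mu, length(I), d, byrow = TRUE)
      Cacc <- Cacc + length(I) * Sigma
      next
    }
    K <- chol2inv(chol(Sigma[O, O, drop = FALSE]))
    B <- Sigma[M, O, drop = FALSE] %*% K
    Ximp[I, M] <- matrix(mu[M], length(I), length(M), byrow = TRUE) +
      Xc[I, O, drop = FALSE] %*% t(B)
    Cacc[M, M] <- Cacc[M, M] + length(I) *
      (Sigma[M, M, drop = FALSE] - B %*% Sigma[O, M, drop = FALSE])
  }
  mu_new <- colMeans(Ximp)
  Xi <- sweep(Ximp, 2, mu_new)
  Sigma_new <- crossprod(Xi) / m + Cacc / m
  dimnames(Sigma_new) <- dimnames(Sigma)
  list(mu = mu_new, Sigma = Sigma_new)
}

# penalized negative log-likelihood over unflagged sub-vectors
cellmcd_objective <- function(X, mu, Sigma, W, q) {
  Xc <- sweep(X, 2, mu)
  key <- pattern_key(W)
  obj <- q * sum(!W)
  for (k in unique(key)) {
    I <- which(key == k)
    O <- which(W[I[1L], ])
    if (length(O) == 0L) next
    ch <- chol(Sigma[O, O, drop = FALSE])
    K <- chol2inv(ch)
    quad <- rowSums((Xc[I, O, drop = FALSE] %*% K) * Xc[I, O, drop = FALSE])
    obj <- obj +
      length(I) * (0.5 * length(O) * log(2 * pi) + sum(log(diag(ch)))) +
      0.5 * sum(quad)
  }
  obj
}

#' Conditional prediction of one coordinate given a subset of others
#'
#' Under a multivariate normal model with the given center and covariance,
#' returns the conditional expectation and conditional standard deviation of
#' coordinate `target` given the observed coordinates of `row`:
#' `prediction = mu_j + Sigma_{j,O} Sigma_{O,O}^{-1} (row_O - mu_O)` and
#' `cond_sd = sqrt(Sigma_{j,j} - Sigma_{j,O} Sigma_{O,O}^{-1} Sigma_{O,j})`.
#' With an empty observed set the marginal `(mu_j, sqrt(Sigma_{j,j}))` is
#' returned.
#'
#' @param center Length-d mean vector.
#' @param covariance d x d positive-definite covariance matrix.
#' @param row Length-d numeric vector of values (only the observed entries
#'   are used).
#' @param observed Integer indices of the conditioning coordinates; must not
#'   contain `target`.
#' @param target Integer index of the coordinate to predict.
#' @return A list with elements `prediction` and `cond_sd`.
#' @examples
#' S <- matrix(c(1, 0.5, 0.5, 1), 2)
#' cell_predict(c(0, 0), S, c(NA, 2), observed = 2, target = 1)
#' @export
cell_predict <- function(center, covariance, row, observed, target) {
  d <- length(center)
  if (length(target) != 1L || target < 1L || target > d)
    zstop("target must be a single coordinate index")
  if (target %in% observed)
    zstop("observed set must not contain the target coordinate")
  if (length(observed) == 0L)
    return(list(prediction = center[target],
                cond_sd = sqrt(covariance[target, target])))
  SOO <- covariance[observed, observed, drop = FALSE]
  K <- tryCatch(chol2inv(chol(clip_pd(SOO, 1e-10))),
                error = function(e) zstop("singular observed block"))
  B <- covariance[target, observed, drop = FALSE] %*% K
  pred <- center[target] +
    as.numeric(B %*% (row[observed] - center[observed]))
  cv <- covariance[target, target] -
    as.numeric(B %*% covariance[observed, target, drop = FALSE])
  list(prediction = pred, cond_sd = sqrt(max(cv, 0)))
}

#' Entry outliers flagged by standardized residual
#'
#' Lists every cell whose absolute standardized residual
#' `|r*_gj| = |z_gj - prediction| / cond_sd` exceeds `cutoff`, sorted by
#' descending absolute residual. The `hidden` indicator marks cells whose
#' raw `|z_gj|` is below the cutoff — associations that look unremarkable on
#' their own but are inconsistent with the gene's other associations.
#'
#' @param fit A [fit_cellmcd()] result.
#' @param cutoff Residual threshold; defaults to the fit's
#'   `residual_cutoff` (`sqrt(penalty_q)`, 2.5758 for the default penalty).
#' @return A tibble with columns `gene`, `phenotype`, `z`, `prediction`,
#'   `cond_sd`, `residual`, `flagged` (1 if the cell was excluded from the
#'   robust estimation) and `hidden`.
#' @export
flag_entries <- function(fit, cutoff = NULL) {
  stopifnot(inherits(fit, "cellmcd_fit"))
  cutoff <- cutoff %||% fit$residual_cutoff
  R <- fit$residuals
  idx <- which(abs(R) > cutoff, arr.ind = TRUE)
  out <- tibble::tibble(
    gene = fit$genes[idx[, 1]],
    phenotype = fit$phenotypes[idx[, 2]],
    z = fit$predictions[idx] + R[idx] * fit$cond_sd[idx],
    prediction = fit$predictions[idx],
    cond_sd = fit$cond_sd[idx],
    residual = R[idx],
    flagged = 1L - fit$flags[idx])
  out$hidden <- abs(out$z) < cutoff
  dplyr::arrange(out, dplyr::desc(abs(.data$residual)))
}

#' Row-outlier statistics against a fixed center and covariance
#'
#' Squared Mahalanobis distance of each full raw row from `center` under
#' `covariance`, with upper-tail chi-square(d) p-values and the standardized
#' criterion `sqrt(h_g / d)`.
#'
#' @inheritParams fisher_rank
#' @param center Length-d center vector.
#' @param covariance d x d positive-definite covariance matrix.
#' @return A ranking tibble in the layout of [fisher_rank()], with
#'   `method = "cellmcd"`.
#' @export
row_outlier_stats <- function(z, center, covariance, bh = FALSE) {
  z <- as_zmatrix(z)
  X <- zmat_values(z)
  d <- ncol(X)
  h <- unname(stats::mahalanobis(X, center, covariance))
  p <- stats::pchisq(h, df = d, lower.tail = FALSE)
  rank_result("cellmcd", z$gene, h, sqrt(h / d), p, bh = bh)
}

#' Consensus gene ranking by robust Mahalanobis distance (cellMCD)
#'
#' Fits the cellwise MCD estimator (unless a fit is supplied) and ranks
#' genes by the squared Mahalanobis distance `h_g` of each full raw row from
#' the robust center under the robust covariance, referred to a chi-square
#' distribution with d degrees of freedom. Flagged cells are *not* masked
#' when computing `h_g`; masking would change the reference distribution.
#'
#' @inheritParams fisher_rank
#' @param fit Optionally, a precomputed [fit_cellmcd()] result for `z`.
#' @param ... Parameters passed to [fit_cellmcd()] when `fit` is `NULL`.
#' @return A ranking tibble in the layout of [fisher_rank()] with
#'   `method = "cellmcd"`; the fit is attached as attribute `"fit"`.
#' @examples
#' set.seed(1)
#' cellmcd_rank(matrix(rnorm(300), 100, 3))
#' @export
cellmcd_rank <- function(z, fit = NULL, bh = FALSE, ...) {
  z <- as_zmatrix(z)
  if (is.null(fit)) fit <- fit_cellmcd(z, ...)
  stopifnot(inherits(fit, "cellmcd_fit"))
  out <- row_outlier_stats(z, fit$center, fit$covariance, bh = bh)
  attr(out, "fit") <- fit
  out
}

#' @export
print.cellmcd_fit <- function(x, ...) {
  cat("cellwise MCD fit: ", length(x$genes), " genes x ",
      length(x$phenotypes), " phenotypes\n", sep = "")
  cat("  flagged cells: ", x$n_flagged, " (",
      sprintf("%.2f%%", 100 * x$n_flagged /
                (length(x$genes) * length(x$phenotypes))), ")\n", sep = "")
  cat("  iterations: ", x$iterations,
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  cat("  robust center:\n")
  print(round(x$center, 4))
  cat("  robust covariance:\n")
  print(round(x$covariance, 4))
  invisible(x)
}

#' Tidy a cellMCD fit into one row per cell
#'
#' @param x A `cellmcd_fit` object.
#' @param ... Unused.
#' @return A long tibble with columns `gene`, `phenotype`, `z`,
#'   `prediction`, `cond_sd`, `residual` and `flagged`.
#' @export
tidy.cellmcd_fit <- function(x, ...) {
  tibble::tibble(
    gene = rep(x$genes, times = length(x$phenotypes)),
    phenotype = rep(x$phenotypes, each = length(x$genes)),
    z = x$predictions + x$residuals * x$cond_sd,
    prediction = as.vector(x$predictions),
    cond_sd = as.vector(x$cond_sd),
    residual = as.vector(x$residuals),
    flagged = 1L - as.vector(x$flags))
}

#' One-row summary of a cellMCD fit
#'
#' @param x A `cellmcd_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `m`, `d`, `n_flagged`, `flag_rate`,
#'   `iterations`, `converged`, `objective` and `consistency_factor`.
#' @export
glance.cellmcd_fit <- function(x, ...) {
  m <- length(x$genes); d <- length(x$phenotypes)
  tibble::tibble(
    m = m, d = d, n_flagged = x$n_flagged,
    flag_rate = x$n_flagged / (m * d),
    iterations = x$iterations, converged = x$converged,
    objective = x$objective_trace[length(x$objective_trace)],
    consistency_factor = x$consistency_factor)
}

#' Plot the standardized residuals of a cellMCD fit
#'
#' Residual-versus-cell index plot with horizontal lines at the residual
#' cutoff; cells beyond the cutoff are the entry outliers reported by
#' [flag_entries()].
#'
#' @param object A `cellmcd_fit` object.
#' @param cutoff Residual cutoff to draw; defaults to the fit's.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cellmcd_fit <- function(object, cutoff = NULL, ...) {
  cutoff <- cutoff %||% object$residual_cutoff
  df <- tidy.cellmcd_fit(object)
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$residual,
                                   colour = .data$phenotype)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-cutoff, cutoff), linetype = 2) +
    ggplot2::labs(x = "cell index", y = "standardized residual r*") +
    ggplot2::theme_minimal()
}
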