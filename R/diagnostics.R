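#' Uniform quantile-quantile data and RMSD lack-of-fit for p-values
#'
#' Compares a collection of p-values with the uniform distribution by
#' pairing each sorted p-value with its empirical distribution function
#' value `EDF(p) = #\{p_j <= p\} / n` (right-continuous, includes self).
#' Well-calibrated p-values fall on the identity line; the vertical
#' root-mean-squared difference `rmsd = sqrt(mean((edf - p)^2))` summarizes
#' the lack of fit.
#'
#' When `lower_bound` is set (e.g. 0.01 to look only at the non-significant
#' bulk), p-values at or below the bound are dropped and the retained ones
#' are compared with the uniform distribution on `(lower_bound, 1]`: the EDF
#' values are rescaled as `lower_bound + (1 - lower_bound) * (i / k)`.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param lower_bound Optional probability; values `<= lower_bound` are
#'   dropped before the comparison.
#' @return An object of class `zscreen_qq`: list with `data` (tibble of
#'   sorted `pvalue` and matched `edf`), `rmsd`, `lower_bound`, `n_total`
#'   and `n_retained`. `tidy()` returns the data, `glance()` the summary,
#'   `autoplot()` the QQ plot.
#' @examples
#' pvalue_qq(c(0.25, 0.5, 0.75, 1))$rmsd  # exact uniform grid: 0
#' @export
pvalue_qq <- function(pvalues, lower_bound = NULL) {
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    zstop("p-values must lie in (0, 1]")
  n_total <- length(pvalues)
  p <- sort(pvalues)
  if (!is.null(lower_bound)) {
    p <- p[p > lower_bound]
    if (length(p) == 0L)
      zstop("no p-values above the lower bound")
  }
  k <- length(p)
  edf <- findInterval(p, p) / k          # #\{<= p\}/k, tie-aware
  if (!is.null(lower_bound)) edf <- lower_bound + (1 - lower_bound) * edf
  structure(list(
    data = tibble::tibble(pvalue = p, edf = edf),
    rmsd = sqrt(mean((edf - p)^2)),
    lower_bound = lower_bound, n_total = n_total, n_retained = k),
    class = "zscreen_qq")
}

#' @export
print.zscreen_qq <- function(x, ...) {
  cat("p-value QQ data: ", x$n_retained, " of ", x$n_total, " p-values",
      if (!is.null(x$lower_bound)) paste0(" (> ", x$lower_bound, ")"),
      "\n  RMSD vs uniform: ", signif(x$rmsd, 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.zscreen_qq <- function(x, ...) x$data

#' @export
glance.zscreen_qq <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_total = x$n_total,
                 n_retained = x$n_retained,
                 lower_bound = x$lower_bound %||% NA_real_)
}

#' @export
autoplot.zscreen_qq <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$pvalue, y = .data$edf)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "p-value", y = "EDF") +
    ggplot2::theme_minimal()
}

#' Calibration experiment: RMSD of the three methods on clean bivariate data
#'
#' Simulates `n` points from a bivariate normal distribution with mean
#' (0, 0), unit standard deviations and correlation `rho`, computes each
#' method's row-outlier p-values (Fisher, SSz, and cellMCD after fitting the
#' robust estimator to the simulated data), and summarizes each method's
#' calibration by the RMSD of its uniform QQ points.
#'
#' The RMSD reported here is the root-mean-square displacement of the QQ
#' points from the identity line accumulated over *both* plot axes — the
#' vertical gap `EDF(p) - p` and the equal-magnitude horizontal gap count
#' separately — i.e. `sqrt(2)` times the vertical-only RMSD that
#' [pvalue_qq()] reports. Under correlation, Fisher's method and SSz assume
#' independent columns and miscalibrate; the robust ellipse adapts to the
#' correlation and stays calibrated.
#'
#' @param n Number of simulated points (rows).
#' @param rho True correlation of the two columns.
#' @param seed Integer seed for the simulation.
#' @return A tibble with columns `method`, `rmsd`, `n`, `rho` and `seed`.
#' @examples
#' \donttest{fit_rmsd_experiment(n = 5000, seed = 1)}
#' @export
fit_rmsd_experiment <- function(n = 10000, rho = 0.5, seed = 1) {
  if (n < 1000) zstop("n must be at least 1000")
  sim <- simulate_fig1(n = n, rho = rho, seed = seed)
  z <- sim$values
  pf <- fisher_rank(z)$pvalue
  ps <- ssz_rank(z)$pvalue
  pc <- cellmcd_rank(z)$pvalue
  tibble::tibble(
    method = c("fisher", "ssz", "cellmcd"),
    rmsd = sqrt(2) * c(pvalue_qq(pf)$rmsd, pvalue_qq(ps)$rmsd,
                       pvalue_qq(pc)$rmsd),
    n = n, rho = rho, seed = seed)
}

#' 99% inclusion boundary of a method in the bivariate plane
#'
#' The closed curve in the (z1, z2) plane on which a method's row-outlier
#' p-value equals `1 - level`. SSz gives a circle of radius
#' `sqrt(qchisq(level, 2))` centered at the origin; cellMCD gives the
#' ellipse `(z - center)' covariance^{-1} (z - center) = qchisq(level, 2)`;
#' Fisher's method gives a "pointed circle" traced numerically by a polar
#' sweep with per-angle bisection in the radius (the contour is star-shaped
#' about the origin by sign symmetry).
#'
#' @param method One of `"fisher"`, `"ssz"`, `"cellmcd"`.
#' @param level Coverage probability (default 0.99).
#' @param center,covariance Robust center and covariance (required for
#'   `method = "cellmcd"`; defaults are the origin and identity).
#' @param n_angles Number of sweep angles (default 720).
#' @return A tibble of class `zscreen_boundary` with columns `z1`, `z2`
#'   forming a closed polyline (first point repeated last), and attributes
#'   `method` and `level`.
#' @examples
#' b <- inclusion_boundary("ssz", 0.99)
#' range(sqrt(b$z1^2 + b$z2^2))  # constant radius 3.0349
#' @export
inclusion_boundary <- function(method = c("fisher", "ssz", "cellmcd"),
                               level = 0.99, center = c(0, 0),
                               covariance = diag(2), n_angles = 720) {
  method <- match.arg(method)
  if (length(center) != 2L || !all(dim(covariance) == 2L))
    zstop("inclusion boundaries are defined for d = 2 only")
  theta <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  U <- cbind(cos(theta), sin(theta))
  q2 <- stats::qchisq(level, 2)
  pts <- switch(method,
    ssz = sqrt(q2) * U,
    cellmcd = {
      L <- chol(covariance)              # z = center + sqrt(q2) * t(L) u
      sweep(sqrt(q2) * U %*% L, 2, center, "+")
    },
    fisher = {
      target <- stats::qchisq(level, 4)
      tfun <- function(z) -2 * sum(log(two_sided_p(z)))
      r <- vapply(seq_len(n_angles), function(i) {
        lo <- 0; hi <- 20
        while (hi - lo > 1e-8) {
          mid <- (lo + hi) / 2
          if (tfun(mid * U[i, ]) < target) lo <- mid else hi <- mid
        }
        (lo + hi) / 2
      }, numeric(1))
      r * U
    })
  out <- tibble::tibble(z1 = pts[, 1], z2 = pts[, 2])
  out <- dplyr::bind_rows(out, out[1, ])  # close the polyline
  structure(out, method = method, level = level,
            class = c("zscreen_boundary", class(out)))
}

#' @export
autoplot.zscreen_boundary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z1, y = .data$z2)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0(attr(object, "method"), " ",
                                 100 * attr(object, "level"),
                                 "% inclusion boundary")) +
    ggplot2::theme_minimal()
}

#' Count genes significant by two methods, one, or both
#'
#' @param a,b Ranking tibbles over the same genes (see [fisher_rank()]).
#' @param threshold Significance threshold on the consensus p-value.
#' @return A one-row tibble with columns `both`, `only_a`, `only_b`,
#'   `neither`, `method_a`, `method_b` and `threshold`.
#' @examples
#' z <- matrix(rnorm(40), 20, 2)
#' overlap_counts(fisher_rank(z), ssz_rank(z))
#' @export
overlap_counts <- function(a, b, threshold = 0.01) {
  if (!identical(a$gene, b$gene))
    zstop("ranking results do not share the same gene list")
  sa <- a$pvalue < threshold
  sb <- b$pvalue < threshold
  tibble::tibble(
    both = sum(sa & sb), only_a = sum(sa & !sb), only_b = sum(!sa & sb),
    neither = sum(!sa & !sb),
    method_a = a$method[1], method_b = b$method[1], threshold = threshold)
}

#' Sub-matrix of the k most significant genes, ordered by rank
#'
#' @param result A ranking tibble (see [fisher_rank()]).
#' @param z The z-matrix the ranking came from.
#' @param k Number of top genes to keep (default 25).
#' @return A z-matrix tibble with `k` rows in rank order.
#' @export
topk_zmatrix <- function(result, z, k = 25) {
  z <- as_zmatrix(z)
  if (k > nrow(z))
    zstop(paste0("k = ", k, " exceeds the number of genes (", nrow(z), ")"))
  top <- result$gene[order(result$rank)][seq_len(k)]
  z[match(top, z$gene), , drop = FALSE]
}
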