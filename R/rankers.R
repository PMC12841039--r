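#' Two-sided standard normal p-value
#'
#' `2 * P(N(0,1) > |z|)`, the two-sided tail probability of a z-statistic.
#' Two-sided p-values treat the resistance and sensitivity directions of an
#' association symmetrically, so Fisher's method built on them is invariant
#' to sign flips, like SSz.
#'
#' @param z Numeric vector of finite z-statistics.
#' @return p-values in (0, 1], floored at 1e-300.
#' @examples
#' two_sided_p(c(0, 1.96, -1.96))
#' @export
two_sided_p <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z)))
    zstop("z-statistics must be finite numbers")
  floor_p(2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

# ranks: ascending p, ties broken by descending statistic then gene ID
rank_with_ties <- function(pvalue, statistic, gene) {
  ord <- order(pvalue, -statistic, gene)
  r <- integer(length(ord))
  r[ord] <- seq_along(ord)
  r
}

rank_result <- function(method, gene, statistic, criterion, pvalue, bh = FALSE) {
  pvalue <- unname(floor_p(pvalue))
  statistic <- unname(statistic)
  out <- tibble::tibble(
    method = method, gene = gene, statistic = statistic,
    criterion = unname(criterion), pvalue = pvalue,
    rank = rank_with_ties(pvalue, statistic, gene))
  if (isTRUE(bh)) out$qvalue <- stats::p.adjust(pvalue, method = "BH")
  out
}

#' Consensus gene ranking by Fisher's method
#'
#' For each gene g computes `t_g = -2 * sum_j log(p_gj)` from the two-sided
#' per-entry p-values `p_gj = two_sided_p(z_gj)` and refers it to a central
#' chi-square distribution with 2d degrees of freedom. The standardized
#' criterion is `t_g / (2d)`, which has expectation 1 under the global null.
#'
#' @param z A z-matrix (data frame or matrix, see [as_zmatrix()]).
#' @param bh If `TRUE`, append a `qvalue` column of Benjamini-Hochberg
#'   adjusted p-values.
#' @return A tibble with columns `method`, `gene`, `statistic`, `criterion`,
#'   `pvalue` and `rank` (1 = most significant; ties broken by descending
#'   statistic, then gene identifier).
#' @seealso [ssz_rank()], [cellmcd_rank()]
#' @examples
#' fisher_rank(matrix(rnorm(20), 10, 2))
#' @export
fisher_rank <- function(z, bh = FALSE) {
  z <- as_zmatrix(z)
  X <- zmat_values(z)
  d <- ncol(X)
  tg <- -2 * rowSums(log(floor_p(two_sided_p_matrix(X))))
  p <- stats::pchisq(tg, df = 2 * d, lower.tail = FALSE)
  rank_result("fisher", z$gene, tg, tg / (2 * d), p, bh = bh)
}

two_sided_p_matrix <- function(X) {
  P <- 2 * stats::pnorm(abs(X), lower.tail = FALSE)
  pmin(pmax(P, P_FLOOR), 1)
}

#' Consensus gene ranking by the sum of squared z-statistics (SSz)
#'
#' For each gene g computes `w_g = sum_j z_gj^2` and refers it to a central
#' chi-square distribution with d degrees of freedom. The standardized
#' criterion is the root mean square z-statistic `RMSZ_g = sqrt(w_g / d)`,
#' which sits on the z scale.
#'
#' @inheritParams fisher_rank
#' @return A tibble in the same layout as [fisher_rank()].
#' @examples
#' ssz_rank(matrix(rnorm(20), 10, 2))
#' @export
ssz_rank <- function(z, bh = FALSE) {
  z <- as_zmatrix(z)
  X <- zmat_values(z)
  d <- ncol(X)
  w <- rowSums(X^2)
  p <- stats::pchisq(w, df = d, lower.tail = FALSE)
  rank_result("ssz", z$gene, w, sqrt(w / d), p, bh = bh)
}
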