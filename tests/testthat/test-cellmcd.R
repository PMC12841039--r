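test_that("cell_predict matches closed forms and a normal-equations oracle", {
  # bivariate conditional: prediction rho * x2, SD sqrt(1 - rho^2)
  for (rho in c(-0.8, 0, 0.5, 0.9)) {
    S <- matrix(c(1, rho, rho, 1), 2)
    for (x2 in c(-2, 0.7, 3)) {
      cp <- cell_predict(c(0, 0), S, c(NA, x2), observed = 2, target = 1)
      expect_equal(cp$prediction, rho * x2, tolerance = 1e-10)
      expect_equal(cp$cond_sd, sqrt(1 - rho^2), tolerance = 1e-10)
    }
  }
  # identity covariance: marginal regardless of observed values
  cp <- cell_predict(c(1, 2, 3), diag(3), c(9, -9, 0), observed = c(2, 3),
                     target = 1)
  expect_equal(cp$prediction, 1)
  expect_equal(cp$cond_sd, 1)
  # empty observed set: marginal fallback
  cp <- cell_predict(c(1, 2), matrix(c(4, 1, 1, 2), 2), c(0, 0),
                     observed = integer(0), target = 1)
  expect_equal(cp$prediction, 1)
  expect_equal(cp$cond_sd, 2)

  # 4-dim: regression coefficients from the normal equations solved directly
  set.seed(5)
  A <- matrix(rnorm(16), 4)
  S <- crossprod(A) + diag(4)
  mu <- c(0.5, -1, 2, 0)
  row <- c(NA, 1.2, -0.7, 2.2)
  beta <- solve(S[2:4, 2:4], S[2:4, 1])
  pred_oracle <- mu[1] + sum(beta * (row[2:4] - mu[2:4]))
  sd_oracle <- sqrt(S[1, 1] - sum(beta * S[1, 2:4]))
  cp <- cell_predict(mu, S, row, observed = 2:4, target = 1)
  expect_equal(cp$prediction, pred_oracle, tolerance = 1e-10)
  expect_equal(cp$cond_sd, sd_oracle, tolerance = 1e-10)

  expect_error(cell_predict(mu, S, row, observed = 1:2, target = 1),
               "must not contain")
})

test_that("cellMCD recovers the generating parameters from clean data", {
  mu <- c(1, 2)
  Sigma <- matrix(c(1, 0.5, 0.5, 1), 2)
  X <- draw_mvn(5000, mu, Sigma, seed = 101)
  fit <- fit_cellmcd(tiny_z(X))
  expect_lt(max(abs(fit$center - mu)), 0.05)
  expect_lt(max(abs(fit$covariance - Sigma)), 0.08)
  # clean data: about 0.1% of cells cross the flag rule, never more than 2%
  expect_lte(fit$n_flagged / length(fit$residuals), 0.02)
  expect_true(fit$converged)
})

test_that("a planted gross cell is flagged with a large residual", {
  X <- draw_mvn(400, c(0, 0, 0), diag(3), seed = 55)
  X[1, 1] <- 20
  fit <- fit_cellmcd(tiny_z(X))
  expect_identical(fit$flags[1, 1], 0L)
  expect_gt(abs(fit$residuals[1, 1]), fit$residual_cutoff)
})

test_that("the objective decreases monotonically and columns keep their budget", {
  sim <- simulate_dataset(d = 4, n = 400, correlation = "A09",
                          mechanism = "entries", perout = 0.05, gamma = 0.5,
                          seed = 9)
  fit <- fit_cellmcd(sim$values)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  m <- length(fit$genes)
  expect_true(all(colSums(fit$flags) >= ceiling(fit$alpha * m)))
})

test_that("with flagging disabled the fit equals the Gaussian MLE", {
  X <- draw_mvn(300, c(0, 1), matrix(c(2, 0.6, 0.6, 1), 2), seed = 3)
  fit <- fit_cellmcd(tiny_z(X), penalty_q = 1e12)
  expect_equal(fit$n_flagged, 0L)
  expect_equal(fit$consistency_factor, 1)
  expect_equal(unname(fit$center), colMeans(X), tolerance = 1e-6)
  mle_cov <- crossprod(sweep(X, 2, colMeans(X))) / nrow(X)
  expect_lt(max(abs(fit$covariance - mle_cov)), 1e-6)
})

test_that("translating the data shifts the center and nothing else", {
  X <- draw_mvn(500, c(0, 0, 0), a09_matrix(3), seed = 21)
  X[3, 2] <- 15
  shift <- c(-2, 5, 0.5)
  f0 <- fit_cellmcd(tiny_z(X))
  f1 <- fit_cellmcd(tiny_z(sweep(X, 2, shift, "+")))
  expect_lt(max(abs(f1$center - (f0$center + shift))), 1e-8)
  expect_lt(max(abs(f1$covariance - f0$covariance)), 1e-8)
  expect_identical(f1$flags, f0$flags)
  expect_lt(max(abs(f1$residuals - f0$residuals)), 1e-7)
})

test_that("1% gross cells barely move the estimates (breakdown behavior)", {
  X <- draw_mvn(5000, rep(0, 4), a09_matrix(4), seed = 77)
  clean <- fit_cellmcd(tiny_z(X))
  Xc <- X
  set.seed(78)
  bad <- sample(length(Xc), round(0.01 * length(Xc)))
  Xc[bad] <- 20
  dirty <- fit_cellmcd(tiny_z(Xc))
  expect_lt(max(abs(dirty$center - clean$center)), 0.05)
  expect_lt(max(abs(dirty$covariance - clean$covariance)), 0.05)
  # the planted cells are flagged as entry outliers
  bad_idx <- arrayInd(bad, dim(Xc))
  expect_true(all(abs(dirty$residuals[bad_idx]) > dirty$residual_cutoff))
})

test_that("row-outlier distances, p-values and ranks follow the Mahalanobis form", {
  # identity covariance: h = 25, chi2_2 survival = exp(-12.5)
  r1 <- row_outlier_stats(tiny_z(matrix(c(3, 4), 1, 2)), c(0, 0), diag(2))
  expect_equal(r1$statistic, 25)
  expect_equal(r1$pvalue, exp(-12.5), tolerance = 1e-12)
  expect_equal(r1$criterion, sqrt(25 / 2))

  # hand-inverted 2x2 covariance: h((1,1)) = 4/3
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  r2 <- row_outlier_stats(tiny_z(matrix(c(1, 1), 1, 2)), c(0, 0), S)
  expect_equal(r2$statistic, 4 / 3, tolerance = 1e-10)

  # a row at the center has h = 0, p = 1
  r3 <- row_outlier_stats(tiny_z(matrix(c(0.5, -1), 1, 2)), c(0.5, -1), S)
  expect_equal(r3$statistic, 0)
  expect_equal(r3$pvalue, 1)

  # cellmcd_rank ties the fit and the ranking together
  sim <- simulate_dataset(d = 3, n = 300, correlation = "A09",
                          mechanism = "rows", perout = 0.05, gamma = 0.5,
                          seed = 13)
  rk <- cellmcd_rank(sim$values)
  fit <- attr(rk, "fit")
  expect_s3_class(fit, "cellmcd_fit")
  expect_equal(rk$statistic,
               unname(mahalanobis(as.matrix(sim$values[, -1]), fit$center,
                                  fit$covariance)),
               tolerance = 1e-10)
  expect_setequal(rk$rank, seq_len(300))
})

test_that("entry-outlier records are sorted, complete and mark hidden cells", {
  fit <- structure(list(
    genes = c("g1", "g2"), phenotypes = c("p1", "p2"),
    residuals = matrix(c(3, -2.6, 0, 1), 2, 2),
    predictions = matrix(c(-2, 0.5, 0, 0), 2, 2),
    cond_sd = matrix(1, 2, 2),
    flags = matrix(c(0L, 1L, 1L, 1L), 2, 2),
    residual_cutoff = sqrt(qchisq(0.99, 1))),
    class = "cellmcd_fit")
  rec <- flag_entries(fit)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$residual, c(3, -2.6))
  expect_equal(rec$z, c(1, -2.1))  # prediction + residual * cond_sd
  # z = 1 is unremarkable on its own -> hidden outlier; z = -2.1 likewise
  expect_true(all(rec$hidden))
  expect_identical(rec$flagged, c(1L, 0L))

  fit$residuals <- matrix(0, 2, 2)
  expect_equal(nrow(flag_entries(fit)), 0)
})

test_that("small inputs and non-convergence are reported, not silently accepted", {
  expect_error(fit_cellmcd(tiny_z(matrix(rnorm(12), 4, 3))), "5\\*d")
  X <- draw_mvn(200, c(0, 0), matrix(c(1, 0.7, 0.7, 1), 2), seed = 31)
  X[1:8, 1] <- 10
  expect_warning(fit <- fit_cellmcd(tiny_z(X), max_iter = 1),
                 "did not converge")
  expect_false(fit$converged)
})
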