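test_that("QQ data reproduces hand-computed EDF values and RMSD", {
  qq <- pvalue_qq(c(0.25, 0.5, 0.75, 1))
  expect_equal(qq$data$edf, c(0.25, 0.5, 0.75, 1))
  expect_identical(qq$rmsd, 0)

  # ties under the <= rule: EDF jumps to 1 for both
  qq2 <- pvalue_qq(c(0.2, 0.2))
  expect_equal(qq2$data$edf, c(1, 1))
  expect_equal(qq2$rmsd, 0.8)

  set.seed(19)
  qq3 <- pvalue_qq(runif(10000))
  expect_lt(qq3$rmsd, 0.02)

  expect_error(pvalue_qq(c(0, 0.5)), "0, 1")
  expect_error(pvalue_qq(c(0.001, 0.005), lower_bound = 0.01), "lower bound")
})

test_that("restricted QQ rescales to the uniform(lower, 1) reference", {
  p <- c(0.005, 0.2, 0.6, 1)
  qq <- pvalue_qq(p, lower_bound = 0.01)
  expect_equal(qq$n_retained, 3)
  expect_equal(qq$data$pvalue, c(0.2, 0.6, 1))
  expect_equal(qq$data$edf, 0.01 + 0.99 * (1:3) / 3)
  expect_equal(qq$rmsd, sqrt(mean((qq$data$edf - qq$data$pvalue)^2)))
})

test_that("inclusion boundaries close and sit on their p-value contour", {
  level <- 0.99
  bs <- inclusion_boundary("ssz", level)
  expect_equal(unname(unlist(bs[1, ])), unname(unlist(bs[nrow(bs), ])))
  radius <- sqrt(bs$z1^2 + bs$z2^2)
  expect_lt(max(abs(radius - sqrt(qchisq(level, 2)))), 1e-9)
  expect_equal(radius[1], 3.0349, tolerance = 1e-4)

  # with identity covariance the robust ellipse is the SSz circle
  bc <- inclusion_boundary("cellmcd", level, center = c(0, 0),
                           covariance = diag(2))
  expect_lt(max(abs(bc$z1 - bs$z1)), 1e-6)
  expect_lt(max(abs(bc$z2 - bs$z2)), 1e-6)

  # a sheared ellipse still sits on the chi-square contour
  S <- matrix(c(2, 0.8, 0.8, 1), 2)
  be <- inclusion_boundary("cellmcd", level, center = c(1, -1), covariance = S)
  hb <- mahalanobis(cbind(be$z1, be$z2), c(1, -1), S)
  expect_lt(max(abs(pchisq(hb, 2, lower.tail = FALSE) - (1 - level))), 1e-6)

  # Fisher boundary: every point on the chi2_4 contour of the Fisher statistic
  bf <- inclusion_boundary("fisher", level)
  tvals <- apply(cbind(bf$z1, bf$z2), 1, function(z)
    -2 * sum(log(two_sided_p(z))))
  expect_lt(max(abs(pchisq(tvals, 4, lower.tail = FALSE) - (1 - level))), 1e-6)
  # axis crossing agrees with an independent 1-D root
  axis_oracle <- uniroot(function(z) -2 * log(2 * pnorm(-z)) - qchisq(level, 4),
                         c(2, 5), tol = 1e-10)$root
  expect_equal(bf$z1[1], axis_oracle, tolerance = 1e-6)

  expect_error(inclusion_boundary("ssz", 0.99, center = c(0, 0, 0),
                                  covariance = diag(3)), "d = 2")
})

test_that("overlap counts partition the gene list", {
  X <- draw_mvn(60, rep(0, 2), diag(2), seed = 4)
  a <- fisher_rank(tiny_z(X))
  oc <- overlap_counts(a, a, threshold = 0.2)
  expect_equal(oc$only_a + oc$only_b, 0)
  expect_equal(oc$both, sum(a$pvalue < 0.2))

  b <- a
  # disjoint significant sets of sizes 2 and 3
  a$pvalue <- rep(1, 60); a$pvalue[1:2] <- 1e-4
  b$pvalue <- rep(1, 60); b$pvalue[3:5] <- 1e-4
  oc2 <- overlap_counts(a, b)
  expect_equal(c(oc2$both, oc2$only_a, oc2$only_b), c(0, 2, 3))
  expect_equal(oc2$both + oc2$only_a + oc2$only_b + oc2$neither, 60)

  a$pvalue <- rep(1, 60); a$pvalue[1:2] <- c(0.001, 0.5)
  b$pvalue <- rep(1, 60); b$pvalue[1:2] <- c(0.001, 0.005)
  oc3 <- overlap_counts(a, b)
  expect_equal(c(oc3$both, oc3$only_a, oc3$only_b), c(1, 0, 1))

  b$gene <- rev(b$gene)
  expect_error(overlap_counts(a, b), "same gene list")
})

test_that("top-k extraction returns rank-ordered rows of the input matrix", {
  fx <- screen_fixture()
  res <- ssz_rank(fx$z)
  top <- topk_zmatrix(res, fx$z, k = 5)
  expect_identical(top$gene, res$gene[order(res$rank)][1:5])
  expect_identical(topk_zmatrix(res, fx$z, k = 1)$gene,
                   res$gene[which.min(res$pvalue)])
  full <- topk_zmatrix(res, fx$z, k = nrow(fx$z))
  expect_setequal(full$gene, fx$z$gene)
  expect_equal(as.matrix(full[match(fx$z$gene, full$gene), -1]),
               as.matrix(fx$z[, -1]), tolerance = 0)
  expect_error(topk_zmatrix(res, fx$z, k = 1000), "exceeds")
})

test_that("under independence all three methods are nearly calibrated", {
  res <- fit_rmsd_experiment(n = 10000, rho = 0, seed = 6)
  expect_true(all(res$rmsd < 0.02))
})

test_that("under correlation the robust ellipse fits where the others do not", {
  res <- fit_rmsd_experiment(n = 10000, rho = 0.5, seed = 14)
  rmsd <- setNames(res$rmsd, res$method)
  expect_lt(rmsd["cellmcd"], rmsd["fisher"])
  expect_lt(rmsd["cellmcd"], rmsd["ssz"])
})
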