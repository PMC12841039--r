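test_that("covariance structures match their definitions", {
  expect_equal(make_sigma("independent", 7), diag(7))
  expect_equal(make_sigma("A09", 3),
               rbind(c(1, -0.9, 0.81), c(-0.9, 1, -0.9), c(0.81, -0.9, 1)))
  S <- make_sigma("ALYZ", 10, seed = 2)
  ev <- eigen(S, symmetric = TRUE)$values
  expect_gte(max(ev) / min(ev), 99)
  expect_lte(max(ev) / min(ev), 101)
  expect_lt(max(abs(diag(S) - 1)), 1e-9)
  expect_identical(S, make_sigma("ALYZ", 10, seed = 2))
  expect_false(identical(S, make_sigma("ALYZ", 10, seed = 3)))
  expect_error(make_sigma("banana", 5))
})

test_that("row contamination hits its count and exact Mahalanobis placement", {
  sim <- simulate_dataset(d = 5, n = 1000, correlation = "A09",
                          mechanism = "rows", perout = 0.05, gamma = 0.5,
                          seed = 3)
  expect_equal(sum(sim$replaced_rows), 50)
  expect_equal(sum(sim$row_labels), 50)
  X <- as.matrix(sim$values[, -1])
  h <- mahalanobis(X[sim$replaced_rows == 1, ], rep(0, 5), sim$sigma_true)
  expect_lt(max(abs(h - (1 + 0.5)^2 * qchisq(0.99, 5))), 1e-8)
})

test_that("entry contamination matches its rate and label bookkeeping", {
  sim <- simulate_dataset(d = 5, n = 2000, correlation = "independent",
                          mechanism = "entries", perout = 0.01, gamma = 0.25,
                          seed = 4)
  ncells <- 2000 * 5
  frac <- sum(sim$cell_labels) / ncells
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / ncells))
  expect_identical(sim$row_labels,
                   as.integer(sim$replaced_rows | rowSums(sim$cell_labels) > 0))
  # contaminated cells sit at the documented magnitude
  X <- as.matrix(sim$values[, -1])
  vals <- abs(X[sim$cell_labels == 1])
  expect_lt(max(abs(vals - (1 + 0.25) * sqrt(qchisq(0.99, 1)))), 1e-8)
})

test_that("datasets are reproducible and the clean draw ignores the mechanism", {
  s1 <- simulate_dataset(d = 3, n = 200, correlation = "ALYZ",
                         mechanism = "both", perout = 0.05, gamma = 0.5,
                         seed = 10)
  s2 <- simulate_dataset(d = 3, n = 200, correlation = "ALYZ",
                         mechanism = "both", perout = 0.05, gamma = 0.5,
                         seed = 10)
  expect_identical(s1$values, s2$values)
  expect_identical(s1$row_labels, s2$row_labels)

  srows <- simulate_dataset(d = 3, n = 200, correlation = "ALYZ",
                            mechanism = "rows", perout = 0.05, gamma = 0.5,
                            seed = 10)
  untouched <- s1$row_labels == 0 & srows$row_labels == 0
  expect_gt(sum(untouched), 100)
  expect_identical(s1$values[untouched, ], srows$values[untouched, ])
})

test_that("the both mechanism splits its budget between rows and cells", {
  sim <- simulate_dataset(d = 5, n = 1000, correlation = "independent",
                          mechanism = "both", perout = 0.05, gamma = 0.5,
                          seed = 12)
  expect_equal(sum(sim$replaced_rows), 25)       # floor(perout * n / 2)
  expect_gt(sum(sim$cell_labels), 0)
  # no cell contamination inside replaced rows
  expect_equal(sum(sim$cell_labels[sim$replaced_rows == 1, ]), 0)
})

test_that("the bivariate calibration draw matches its moments", {
  sim <- simulate_fig1(n = 10000, rho = 0.5, seed = 1)
  X <- as.matrix(sim$values[, -1])
  expect_lt(abs(cor(X[, 1], X[, 2]) - 0.5), 0.03)
  expect_lt(max(abs(colMeans(X))), 0.04)
  expect_equal(sum(sim$row_labels), 0)

  sim0 <- simulate_fig1(n = 10000, rho = 0, seed = 2)
  X0 <- as.matrix(sim0$values[, -1])
  expect_lt(abs(cor(X0[, 1], X0[, 2])), 0.03)
})

test_that("the full design grid enumerates 72 settings", {
  g <- simulation_grid()
  expect_equal(nrow(g), 72)
  expect_equal(nrow(dplyr::distinct(g)), 72)
  expect_setequal(unique(g$d), c(5L, 10L))
  expect_setequal(unique(g$correlation), c("independent", "ALYZ", "A09"))
})
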