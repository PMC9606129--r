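test_that("lagged model estimation recovers known second-order structure", {
  set.seed(101)
  # independent unit-variance noise: cross-covariance vanishes
  w <- matrix(rnorm(3000 * 3), ncol = 3)
  m <- estimate_lagged_model(w, tau = 1)
  expect_equal(m$cov_past, diag(3) + diag(3) * m$ridge,
               tolerance = 0.15, ignore_attr = TRUE)
  expect_lt(max(abs(m$cross_cov)), 0.1)
  expect_equal(m$n_samples, 2999)

  # AR(1) with a = 0.8: lag-1 autocorrelation 0.8 (closed-form oracle)
  a <- 0.8
  x <- as.numeric(arima.sim(list(ar = a), n = 20000))
  w2 <- cbind(x, rnorm(20000))
  m2 <- estimate_lagged_model(w2, tau = 1)
  expect_equal(m2$cross_cov[1, 1] / m2$cov_past[1, 1], a, tolerance = 0.02)
})

test_that("degenerate windows are rejected with informative errors", {
  w <- cbind(rnorm(100), rep(1, 100), rnorm(100))
  colnames(w) <- c("RES", "ECG", "EDA")
  expect_error(estimate_lagged_model(w, tau = 1, ridge = 0), "ECG")
  expect_error(estimate_lagged_model(matrix(rnorm(20), ncol = 2), tau = 9),
               "too short")
  expect_error(estimate_lagged_model(matrix(rnorm(50), ncol = 1), tau = 1),
               "2 channels")
})

test_that("mutual information matches closed forms and a sampling oracle", {
  # zero cross-covariance: independence, MI = 0
  m0 <- lagged_model(diag(3), diag(3), matrix(0, 3, 3))
  expect_equal(mutual_information(m0), 0, tolerance = 1e-12)

  # single channel with lagged correlation 0.5: -log(1 - 0.25) / 2
  m1 <- lagged_model(matrix(1), matrix(1), matrix(0.5))
  expect_equal(mutual_information(m1), -0.5 * log(1 - 0.25), tolerance = 1e-9)

  # random 3-node model vs Monte-Carlo entropy estimate
  set.seed(7)
  m <- rand_var_model(3)
  mc <- mi_mc(m, N = 2e5)
  expect_lt(abs(mutual_information(m) - mc$est), 4 * mc$se)

  # singular joint covariance: advice to use a ridge
  ms <- lagged_model(diag(2), diag(2), diag(2))
  expect_error(mutual_information(ms), "ridge")
})

test_that("mismatched decoding information obeys its limits", {
  set.seed(21)
  bp <- bipartition(1, 2)
  # block-diagonal joint covariance: decoder is exact, I~(1) equals MI
  mb <- var1_population_model(diag(c(0.6, 0.4)), tau = 1)
  expect_equal(mismatched_information(mb, bp, 1), mutual_information(mb),
               tolerance = 1e-10)

  # beta -> 0+: no information
  m <- rand_var_model(2)
  expect_equal(mismatched_information(m, bp, 1e-9), 0, tolerance = 1e-6)

  # I~(beta) <= MI for all beta, across models
  for (i in 1:10) {
    m <- rand_var_model(sample(2:4, 1))
    n <- n_channels(m)
    bp_i <- enumerate_bipartitions(n)[[1]]
    mi <- mutual_information(m)
    for (beta in c(0.1, 0.5, 1, 2, 8, 32)) {
      expect_lte(mismatched_information(m, bp_i, beta), mi + 1e-8)
    }
  }
})

test_that("closed-form I~(beta) agrees with the sampling/quadrature oracle", {
  set.seed(33)
  A <- matrix(c(0.6, 0.3, 0.2, 0.5), 2, 2, byrow = TRUE)
  m <- var1_population_model(A, tau = 1)
  bp <- bipartition(1, 2)
  for (beta in c(0.5, 1)) {
    mc <- itilde_mc_2node(m, beta, N = 1e5)
    expect_lt(abs(mismatched_information(m, bp, beta) - mc$est), 3 * mc$se)
  }
})

test_that("R and C++ evaluations of I~(beta) coincide", {
  set.seed(55)
  for (i in 1:8) {
    n <- sample(2:5, 1)
    m <- rand_var_model(n)
    parts <- enumerate_bipartitions(n)
    for (bp in parts[sample(length(parts), min(3, length(parts)))]) {
      beta <- runif(1, 0.05, 10)
      r_val <- mismatched_information(m, bp, beta)
      c_val <- phistar:::cpp_itilde(m$cov_past, m$cov_present, m$cross_cov,
                                    list(bp$block_a, bp$block_b), beta)
      expect_equal(r_val, c_val, tolerance = 1e-9)
    }
  }
})

test_that("phi_star is bounded by [0, MI] and vanishes for block-diagonal systems", {
  set.seed(77)
  bp <- bipartition(1, 2)
  mb <- var1_population_model(diag(c(0.7, 0.3)), tau = 1)
  expect_equal(phi_star(mb, bp)$phi, 0, tolerance = 1e-8)

  A <- matrix(c(0.5, 0.25, 0.25, 0.5), 2, 2)
  m <- var1_population_model(A, tau = 1)
  res <- phi_star(m, bp)
  expect_gt(res$phi, 0)
  expect_lte(res$phi, res$mutual_info + 1e-8)

  # phi equals MI minus the Monte-Carlo maximum of I~(beta) over a beta grid
  mc_best <- max(vapply(c(0.5, 0.8, 1, 1.3, 2),
                        function(b) itilde_mc_2node(m, b, N = 5e4)$est, 0))
  expect_lt(abs(res$phi - (res$mutual_info - mc_best)), 0.015)
})

test_that("MIP search enumerates all bipartitions and finds the weakest link", {
  expect_length(enumerate_bipartitions(7), 63)
  keys <- vapply(enumerate_bipartitions(4), format_bipartition, "")
  expect_length(unique(keys), 7)

  # block-diagonal w.r.t. {7} vs rest: that cut has Phi = 0 and is the MIP
  A <- default_coupling()
  A[7, -7] <- 0; A[-7, 7] <- 0
  m <- var1_population_model(A, tau = 1, labels = phistar_channels)
  res <- mip_search(m)
  expect_equal(res$phi_mip, 0, tolerance = 1e-8)
  expect_equal(res$mip$block_b, 7L)
  expect_equal(nrow(res$per_partition), 63)
  # exhaustiveness: the reported minimum really is the minimum
  expect_true(all(res$phi_mip <= res$per_partition$phi + 1e-12))

  # 2-node: single candidate, equal to phi_star of it
  m2 <- var1_population_model(matrix(c(0.5, 0.2, 0.2, 0.5), 2), tau = 1)
  r2 <- mip_search(m2)
  expect_equal(nrow(r2$per_partition), 1)
  expect_equal(r2$phi_mip, phi_star(m2, bipartition(1, 2))$phi, tolerance = 1e-10)
})

test_that("bipartitions are canonical and validated", {
  bp <- bipartition(c(3, 2), c(4, 1))
  expect_equal(bp$block_a, c(1L, 4L))  # block with node 1 is block_a
  expect_equal(bp$block_b, c(2L, 3L))
  expect_error(bipartition(1:2, 2:3), "disjoint")
  expect_error(bipartition(1:2, integer(0)), "non-empty")
  expect_error(bipartition(1, 3), "partition")
  expect_equal(format_bipartition(bp, c("a", "b", "c", "d")), "a,d|b,c")
})
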