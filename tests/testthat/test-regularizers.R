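test_that("zero-order Tikhonov matches identity cases and dense solves", {
  bi <- svd_bundle(diag(4), c(4, 3, 2, 1))
  expect_equal(solve_zot(bi, 0)$x, c(4, 3, 2, 1))
  expect_equal(solve_zot(bi, 1)$x, c(4, 3, 2, 1) / 2)   # every filter 1/2

  for (seed in 1:5) {
    s <- random_system(seed, m = 20, n = 10)
    bu <- svd_bundle(s$A, s$b)
    for (lam in c(0.1, 1)) {
      expect_equal(solve_zot(bu, lam)$x, dense_tikhonov(s$A, s$b, lam),
                   tolerance = 1e-10)
    }
    expect_equal(solve_zot(bu, 0)$x, drop(qr.solve(s$A, s$b)),
                 tolerance = 1e-8)
  }
  rk <- svd_bundle(diag(c(1, 0)), c(1, 1))
  expect_error(solve_zot(rk, 0), "zero singular value")
})

test_that("first-order solution agrees with zero-order at L = I and with
           dense generalized solves", {
  for (seed in 1:5) {
    s <- random_system(seed, m = 15, n = 8, with_L = TRUE)
    bu <- svd_bundle(s$A, s$b)
    gi <- gsvd_bundle(s$A, diag(8), s$b)
    for (lam in c(0, 0.05, 0.5, 5))
      expect_equal(solve_first_order(gi, lam)$x, solve_zot(bu, lam)$x,
                   tolerance = 1e-8)
    g <- gsvd_bundle(s$A, s$L, s$b)
    for (lam in c(0.05, 0.5))
      expect_equal(solve_first_order(g, lam)$x,
                   dense_tikhonov(s$A, s$b, lam, s$L), tolerance = 1e-8)
  }
})

test_that("weight matrix follows the half-quadratic formula", {
  D <- diag(3)
  expect_equal(build_weight_matrix(D, c(0, 0, 0), 1e-5),
               rep(1 / (2 * sqrt(1e-5)), 3))
  w <- build_weight_matrix(D, c(3, 1, 0.1), 1e-5)
  expect_equal(w[1], 1 / (2 * sqrt(9 + 1e-5)))
  expect_true(all(diff(w) > 0))              # decreasing in |Dx|
  expect_true(all(w > 0 & w <= 1 / (2 * sqrt(1e-5))))
  expect_error(build_weight_matrix(D, rep(0, 3), -1), "beta")
})

test_that("L1 current-density solve matches dense normal equations and its
           algebraic special cases", {
  s <- random_system(11, m = 16, n = 7)
  D <- matrix(stats::rnorm(49), 7, 7)
  lam <- 0.3; beta <- 1e-5
  rec <- solve_l1_current_density(s$A, s$b, D, lam, beta,
                                  zot_seed_lambda = 0.2)
  w <- build_weight_matrix(D, rec$x0, beta)
  Dt <- sqrt(w) * D
  expect_equal(rec$x, dense_tikhonov(s$A, s$b, lam, Dt), tolerance = 1e-8)

  # D = 0: penalty vanishes, unregularized least squares for every lambda
  rec0 <- solve_l1_current_density(s$A, s$b, matrix(0, 7, 7), 2, beta,
                                   zot_seed_lambda = 0.2)
  expect_equal(rec0$x, drop(qr.solve(s$A, s$b)), tolerance = 1e-8)

  # D x0 = 0: uniform weights, equivalent to operator D at
  # lambda_eff = lambda / sqrt(2 sqrt(beta))
  Dn <- D - tcrossprod(D %*% rec$x0, rec$x0) / sum(rec$x0^2)  # D x0 = 0
  recu <- solve_l1_current_density(s$A, s$b, Dn, lam, beta,
                                   zot_seed_lambda = 0.2)
  lam_eff <- lam / sqrt(2 * sqrt(beta))
  expect_equal(recu$x, dense_tikhonov(s$A, s$b, lam_eff, Dn),
               tolerance = 1e-8)

  # squared-weight variant uses W D
  recw <- solve_l1_current_density(s$A, s$b, D, lam, beta,
                                   zot_seed_lambda = 0.2,
                                   weight_form = "squared")
  expect_equal(recw$x, dense_tikhonov(s$A, s$b, lam, w * D),
               tolerance = 1e-8)
})

test_that("solution norms are monotone in lambda and residuals complementary", {
  s <- random_system(7, m = 20, n = 10)
  bu <- svd_bundle(s$A, s$b)
  grid <- exp(seq(log(1e-4), log(10), length.out = 60))
  norms <- vapply(grid, function(l) sqrt(sum(solve_zot(bu, l)$x^2)),
                  numeric(1))
  resid <- vapply(grid, function(l)
    sqrt(sum((s$A %*% solve_zot(bu, l)$x - s$b)^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
  expect_true(all(diff(resid) >= -1e-10))
})
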