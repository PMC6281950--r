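test_that("svd bundle satisfies its reconstruction invariants", {
  b5 <- svd_bundle(diag(5), 1:5)
  expect_equal(b5$sigma, rep(1, 5))
  expect_equal(drop(b5$coef), as.numeric(1:5))

  bd <- svd_bundle(diag(c(3, 2, 1)), c(1, 1, 1))
  expect_equal(bd$sigma, c(3, 2, 1))

  s <- random_system(1, m = 20, n = 10)
  bu <- svd_bundle(s$A, s$b)
  expect_lt(norm(s$A - bu$u %*% diag(bu$sigma) %*% t(bu$v), "F") /
              norm(s$A, "F"), 1e-10)
  expect_lt(norm(crossprod(bu$u) - diag(10), "F"), 1e-10)
  expect_lt(norm(crossprod(bu$v) - diag(10), "F"), 1e-10)
  expect_true(all(diff(bu$sigma) <= 0))
  expect_error(svd_bundle(matrix(NA_real_, 3, 2), 1:3), "non-finite")
})

test_that("gsvd bundle reconstructs A and L and reduces to the SVD at L = I", {
  # A = I, L = I: symmetry forces sigma = nu = 1/sqrt(2), gsv = 1
  g4 <- gsvd_bundle(diag(4), diag(4), rep(1, 4))
  expect_equal(g4$sigma, rep(1 / sqrt(2), 4), tolerance = 1e-12)
  expect_equal(g4$nu, rep(1 / sqrt(2), 4), tolerance = 1e-12)
  expect_equal(g4$gsv, rep(1, 4), tolerance = 1e-12)

  for (seed in 1:5) {
    s <- random_system(seed, m = 15, n = 8, with_L = TRUE)
    g <- gsvd_bundle(s$A, s$L, s$b)
    expect_lt(norm(s$A - g$P %*% diag(g$sigma) %*% g$Zinv, "F") /
                norm(s$A, "F"), 1e-8)
    expect_lt(norm(s$L - g$Q %*% diag(g$nu) %*% g$Zinv, "F") /
                norm(s$L, "F"), 1e-8)
    expect_lt(max(abs(g$sigma^2 + g$nu^2 - 1)), 1e-8)
    expect_true(all(diff(g$sigma) >= -1e-12))
    expect_true(all(diff(g$nu) <= 1e-12))
    # L = I: generalized singular values equal ordinary singular values
    gi <- gsvd_bundle(s$A, diag(8), s$b)
    sv <- svd(s$A)$d
    expect_equal(sort(gi$gsv), sort(sv), tolerance = 1e-8)
  }
  s <- random_system(9, m = 10, n = 5)
  expect_error(gsvd_bundle(s$A[, c(1, 1, 2, 3, 4)] * 0, diag(5) * 0, s$b),
               "rank")
})

test_that("residual and seminorm curves match dense Tikhonov solves", {
  for (seed in 1:5) {
    s <- random_system(seed, m = 12, n = 7)
    bu <- svd_bundle(s$A, s$b)
    for (lam in c(0.03, 0.3, 3)) {
      x <- dense_tikhonov(s$A, s$b, lam)
      expect_equal(residual_curve(bu, lam), sum((s$A %*% x - s$b)^2),
                   tolerance = 1e-9)
      expect_equal(seminorm_curve(bu, lam), sum(x^2), tolerance = 1e-9)
    }
    sg <- random_system(seed + 100, m = 15, n = 8, with_L = TRUE)
    g <- gsvd_bundle(sg$A, sg$L, sg$b)
    for (lam in c(0.05, 0.5)) {
      x <- dense_tikhonov(sg$A, sg$b, lam, sg$L)
      expect_equal(residual_curve(g, lam), sum((sg$A %*% x - sg$b)^2),
                   tolerance = 1e-8)
      expect_equal(seminorm_curve(g, lam), sum((sg$L %*% x)^2),
                   tolerance = 1e-8)
    }
  }
})

test_that("curve limits: lambda = 0 gives the least-squares residual, large
           lambda gives ||b||^2 and vanishing seminorm", {
  s <- random_system(4, m = 9, n = 9)
  bu <- svd_bundle(s$A, s$b)
  expect_equal(residual_curve(bu, 0), 0, tolerance = 1e-16)
  expect_equal(seminorm_curve(bu, 0), sum(solve(s$A, s$b)^2),
               tolerance = 1e-6)
  big <- 1e9
  expect_equal(residual_curve(bu, big), sum(s$b^2), tolerance = 1e-6)
  expect_lt(seminorm_curve(bu, big), 1e-12)
})

test_that("influence trace equals the dense trace and hits its limits", {
  s <- random_system(2, m = 14, n = 6)
  bu <- svd_bundle(s$A, s$b)
  expect_equal(influence_trace(bu, 0), 6, tolerance = 1e-10)  # full rank: n
  expect_lt(influence_trace(bu, 1e9), 1e-12)
  for (lam in c(0.1, 1)) {
    H <- s$A %*% solve(crossprod(s$A) + lam^2 * diag(6), t(s$A))
    expect_equal(influence_trace(bu, lam), sum(diag(H %*% H)),
                 tolerance = 1e-9)
  }
})

test_that("rho is nondecreasing and eta nonincreasing on the shared grid", {
  for (seed in 1:5) {
    s <- random_system(seed + 20, m = 18, n = 9)
    bu <- svd_bundle(s$A, s$b)
    grid <- lambda_grid(bu, n_points = 200)
    expect_true(all(diff(residual_curve(bu, grid)) >= -1e-12))
    expect_true(all(diff(seminorm_curve(bu, grid)) <= 1e-12))
    expect_true(all(diff(influence_trace(bu, grid)) <= 1e-12))
  }
})

test_that("lambda grid is geometric, increasing and spans the spectrum", {
  s <- random_system(3)
  bu <- svd_bundle(s$A, s$b)
  g <- lambda_grid(bu)
  expect_length(g, 300)
  expect_true(all(diff(g) > 0))
  expect_equal(g[1], 1e-8 * max(bu$sigma))
  expect_equal(g[300], 10 * max(bu$sigma))
  expect_equal(sd(diff(log(g))), 0, tolerance = 1e-10)
})
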