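test_that("GCV values match the dense influence-matrix definition", {
  for (seed in 1:5) {
    s <- random_system(seed, m = 15, n = 8)
    bu <- svd_bundle(s$A, s$b)
    sc <- selection_curve(bu, lambda = c(0.05, 0.3, 2))
    for (k in 1:3) {
      lam <- sc$lambda[k]
      H <- s$A %*% solve(crossprod(s$A) + lam^2 * diag(8), t(s$A))
      x <- dense_tikhonov(s$A, s$b, lam)
      Gd <- sum((s$A %*% x - s$b)^2) / sum(diag(diag(15) - H))^2
      expect_equal(sc$G[k], Gd, tolerance = 1e-9)
    }
    # closed-form large-lambda limit ||b||^2 / m^2
    expect_equal(selection_curve(bu, lambda = c(1e8, 2e8))$G,
                 rep(sum(s$b^2) / 15^2, 2), tolerance = 1e-6)
  }
})

test_that("grid argmin of GCV matches exhaustive evaluation on a fixture", {
  A <- diag(c(1, 0.1)); b <- c(1, 1)
  bu <- svd_bundle(A, b)
  grid <- exp(seq(log(1e-4), log(10), length.out = 1000))
  ch <- gcv_lambda(bu, lambda = grid)
  G <- selection_curve(bu, lambda = grid)$G
  expect_equal(ch$index, max(which(G <= min(G) + 1e-12 * abs(min(G)))))
  expect_equal(ch$lambda, grid[ch$index])
})

test_that("RGCV reduces to GCV at gamma = 1 and to xi * G at gamma = 0", {
  s <- random_system(8, m = 15, n = 8)
  bu <- svd_bundle(s$A, s$b)
  grid <- lambda_grid(bu)
  sc1 <- selection_curve(bu, lambda = grid, gamma = 1)
  expect_equal(sc1$R, sc1$G)
  expect_equal(rgcv_lambda(bu, gamma = 1, lambda = grid)$lambda,
               gcv_lambda(bu, lambda = grid)$lambda)
  sc0 <- selection_curve(bu, lambda = grid, gamma = 0)
  expect_equal(sc0$R, sc0$xi * sc0$G)
  sch <- selection_curve(bu, lambda = grid, gamma = 0.4)
  expect_equal(sch$R, (0.4 + 0.6 * sch$xi) * sch$G)
})

test_that("RGCV's choice is stable in gamma on phantom frames", {
  ph <- default_phantom()
  sys <- default_fem()
  bu <- svd_bundle(sys$A, ph$b_noisy)
  for (fr in c(15, 30, 45)) {
    lams <- vapply(c(0, 0.25, 0.5), function(g)
      rgcv_lambda(bu, frame = fr, gamma = g)$lambda, numeric(1))
    expect_lt(log10(max(lams) / min(lams)), 1)   # within one grid decade
  }
})

test_that("CRESO spectral formula matches a finite difference of the
           composite functional", {
  for (seed in 1:5) {
    s <- random_system(seed + 40, m = 15, n = 8)
    bu <- svd_bundle(s$A, s$b)
    lams <- c(0.05, 0.2, 1)
    C <- selection_curve(bu, lambda = lams)$C
    for (k in seq_along(lams)) {
      l2 <- lams[k]^2
      h <- 1e-6 * max(l2, 1e-12)
      f <- function(t) {
        lam <- sqrt(t)
        t * seminorm_curve(bu, lam) - residual_curve(bu, lam)
      }
      fd <- (f(l2 + h) - f(l2 - h)) / (2 * h)
      expect_equal(C[k], fd, tolerance = 1e-5)
    }
  }
})

test_that("CRESO finds a constructed interior peak and agrees across
           SVD/GSVD branches at L = I", {
  # small spectrum whose C has one interior local maximum inside the
  # transition window; the expected index comes from an independent
  # sign-change scan of the curve
  sig <- c(1, 0.2, 0.04, 0.01); mu <- c(1, 0.1, 0.05, 0.05)
  A <- diag(sig); bu <- svd_bundle(A, mu)
  grid <- exp(seq(log(min(sig)^(2 / 3)), log(max(sig)^(2 / 3)),
                  length.out = 400))
  C <- selection_curve(bu, lambda = grid)$C
  peak <- which(diff(sign(diff(C))) == -2) + 1L
  ch <- creso_lambda(bu, lambda = grid)
  expect_equal(ch$index, peak[1])

  gi <- gsvd_bundle(A, diag(4), mu)
  chg <- creso_lambda(gi, lambda = grid)
  expect_lte(abs(chg$index - ch$index), 1)    # within one grid step
})

test_that("U-curve minimizer lies in the singular-value interval and equals
           the dense-solve objective", {
  for (seed in 1:4) {
    s <- random_system(seed + 60, m = 15, n = 8)
    bu <- svd_bundle(s$A, s$b)
    ch <- ucurve_lambda(bu)
    lo <- min(bu$sigma)^(2 / 3); hi <- max(bu$sigma)^(2 / 3)
    expect_gte(ch$lambda, lo)
    expect_lte(ch$lambda, hi)
    # U values equal 1/||Ax-b||^2 + 1/||x||^2 from dense solves
    for (lam in c(ch$lambda, hi)) {
      x <- dense_tikhonov(s$A, s$b, lam)
      u_dense <- 1 / sum((s$A %*% x - s$b)^2) + 1 / sum(x^2)
      u_spec <- selection_curve(bu, lambda = c(lam, 2 * lam))$Ucurve[1]
      expect_equal(u_spec, u_dense, tolerance = 1e-6)
    }
    # minimality against the interval endpoints on the grid
    w <- which(ch$curve$lambda >= lo & ch$curve$lambda <= hi)
    expect_lte(ch$curve$Ucurve[ch$index], min(ch$curve$Ucurve[w][1],
                                              rev(ch$curve$Ucurve[w])[1]))
  }
})

test_that("ADPC returns the per-frame alpha and the median across frames", {
  n <- 12
  sig <- 10^(-0.4 * (1:n))
  A <- diag(sig)
  # frame built to break the discrete Picard condition at index 7:
  # coefficients decay faster than sigma up to 7, then sit at a constant
  # far above the remaining singular values
  mu <- c(sig[1:7]^1.5, rep(sig[8] * 50, n - 7))
  bu <- svd_bundle(A, mu)        # U = I so u_i'b = mu_i
  ch <- adpc_lambda(bu)
  expect_equal(ch$lambda, sig[7])
  expect_equal(length(ch$alpha), 1)

  # three frames with known alphas -> median
  mu3 <- cbind(c(sig[1:3]^1.5, rep(sig[4] * 50, n - 3)),
               c(sig[1:5]^1.5, rep(sig[6] * 50, n - 5)),
               c(sig[1:9]^1.5, rep(sig[10] * 50, n - 9)))
  ch3 <- adpc_lambda(svd_bundle(A, mu3))
  expect_equal(ch3$lambda, sort(ch3$alpha)[2])
  expect_equal(ch3$lambda, sig[5])

  # all-zero frames are skipped with a warning; all skipped is an error
  expect_warning(ch0 <- adpc_lambda(svd_bundle(A, cbind(mu, 0 * mu))),
                 "skipped")
  expect_equal(ch0$lambda, sig[7])
  expect_error(suppressWarnings(adpc_lambda(svd_bundle(A, 0 * mu))))
  expect_error(adpc_lambda(bu, degree = 4))
})

test_that("criteria choices are invariant to a joint rescaling of A and b", {
  s <- random_system(17, m = 15, n = 8)
  bu1 <- svd_bundle(s$A, s$b)
  bu2 <- svd_bundle(5 * s$A, 5 * s$b)
  g1 <- lambda_grid(bu1); g2 <- lambda_grid(bu2)
  for (crit in c("GCV", "RGCV", "CRESO", "UCurve")) {
    c1 <- choose_lambda(crit, bu1, lambda = g1)
    c2 <- choose_lambda(crit, bu2, lambda = g2)
    # identical up to floating-point jitter inside a flat basin
    expect_lte(abs(c1$index - c2$index), 10)
  }
  # ADPC's chosen index is scale invariant as well (alphas scale with sigma)
  a1 <- adpc_lambda(bu1); a2 <- adpc_lambda(bu2)
  expect_equal(a2$lambda / a1$lambda, 5, tolerance = 1e-9)
})

test_that("GCV's flat-minimum warning fires on noise-free FEM frames", {
  # the severely ill-conditioned FEM transfer with clean data leaves G
  # nearly constant over decades of small lambda: the minimum is
  # ill-determined and must be flagged
  ph <- default_phantom()
  bu <- svd_bundle(default_fem()$A, ph$b_clean)
  flat <- vapply(seq_len(ncol(ph$b_clean)), function(t)
    "flat" %in% gcv_lambda(bu, frame = t)$flags, logical(1))
  expect_true(any(flat))
})
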