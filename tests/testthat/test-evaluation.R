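test_that("relative error and correlation match hand arithmetic", {
  x <- c(1, 2, 3)
  expect_equal(relative_error(x, x), 0)
  expect_equal(correlation_coefficient(x, x), 1)
  expect_equal(relative_error(-x, x), 2)
  expect_equal(correlation_coefficient(-x, x), -1)

  xe <- c(1, 2, 4)
  # ||(0,0,-1)|| / ||(1,2,4)|| and centered cosine, by hand
  expect_equal(relative_error(x, xe), 1 / sqrt(21))
  cc_hand <- sum((x - 2) * (xe - 7 / 3)) /
    sqrt(sum((x - 2)^2) * sum((xe - 7 / 3)^2))
  expect_equal(correlation_coefficient(x, xe), cc_hand)

  expect_error(relative_error(x, c(0, 0, 0)), "zero norm")
  expect_error(correlation_coefficient(x, c(1, 1, 1)), "zero-variance")
})

test_that("CC is affine invariant and RE scale invariant", {
  set.seed(5)
  for (k in 1:10) {
    xc <- rnorm(20); xe <- rnorm(20)
    a <- runif(1, 0.1, 5); cst <- rnorm(1)
    expect_equal(correlation_coefficient(a * xc + cst, xe),
                 correlation_coefficient(xc, xe), tolerance = 1e-12)
    expect_equal(relative_error(a * xc, a * xe), relative_error(xc, xe),
                 tolerance = 1e-12)
  }
})

test_that("transfer residual reports the forward inconsistency", {
  s <- random_system(3, m = 10, n = 6)
  x <- rnorm(6)
  b <- drop(s$A %*% x)
  expect_equal(transfer_residual(s$A, x, b), 0)
  expect_equal(transfer_residual(s$A, x, 2 * b), 0.5)
  expect_error(transfer_residual(s$A, x, 0 * b), "zero norm")
  # 20 dB additive noise realizes RE_d = 0.1 by construction
  bn <- add_noise(matrix(b, 10, 1), 20, seed = 1)
  expect_equal(transfer_residual(s$A, x, drop(bn)), 0.1 / (1),
               tolerance = 0.02)
})

test_that("ischemic-electrode thresholding applies the plateau rule", {
  sig <- matrix(0, 4, 300)
  sig[, 260] <- c(1.0, 0.6, 0.4, 0.1)
  expect_equal(threshold_ischemic_electrodes(sig, pacing_time = 10,
                                             plateau_offset = 250),
               c(3L, 4L))
  # all-equal positive plateau: every electrode exceeds half the max
  sig[, 260] <- 1
  expect_error(threshold_ischemic_electrodes(sig, 10), "all electrodes")
  # all-zero plateau: nothing exceeds the threshold
  sig[, 260] <- 0
  expect_equal(threshold_ischemic_electrodes(sig, 10), 1:4)
  expect_error(threshold_ischemic_electrodes(sig, 100), "outside")
})

test_that("harmonic interpolation reproduces knowns, constants and planar
           linear fields", {
  m <- icosphere(1, 1)
  vals <- rnorm(42)
  expect_equal(interpolate_missing(m, 1:42, vals), vals)
  filled <- interpolate_missing(m, c(3, 17, 30), c(2, 2, 2))
  expect_equal(filled, rep(2, 42), tolerance = 1e-9)

  # planar triangulated strip: harmonic interpolation with cotangent weights
  # reproduces linear fields exactly
  gx <- rep(0:4, 3); gy <- rep(0:2, each = 5)
  verts <- cbind(gx, gy, 0)
  tri <- NULL
  for (r in 0:1) for (cidx in 0:3) {
    a <- r * 5 + cidx + 1
    tri <- rbind(tri, c(a, a + 1, a + 5), c(a + 1, a + 6, a + 5))
  }
  patch <- structure(list(vertices = verts, triangles = tri,
                          vertex_normals = NULL, role = "heart"),
                     class = "surface_mesh")
  boundary <- which(gx %in% c(0, 4) | gy %in% c(0, 2))
  f <- 2 * gx + 0.5
  out <- interpolate_missing(patch, boundary, f[boundary])
  expect_equal(out, f, tolerance = 1e-6)
  expect_error(interpolate_missing(m, integer(0), numeric(0)), "no known")
})

test_that("pacing-site detection finds extrema with deterministic ties and
           reports indeterminate frames", {
  pot <- c(0, -3, -1, 0.5)
  expect_equal(detect_pacing_site(pot), 2L)
  expect_equal(detect_pacing_site(-pot, polarity = "max"), 2L)
  expect_equal(detect_pacing_site(c(0, -3, -3, 1)), 2L)   # lowest index tie
  expect_true(is.na(detect_pacing_site(rep(1, 5) + 1e-9 * (1:5))))
  # dvdt rule uses the following frame
  P <- cbind(c(0, 0, 0), c(-5, -1, 0))
  expect_equal(detect_pacing_site(P, polarity = "dvdt", frame = 1), 1L)
})

test_that("localization error delegates to the mesh geodesic", {
  m <- icosphere(1, 1)
  expect_equal(localization_error(m, 7, 7), 0)
  e <- mesh_edges(m)[1, ]
  expect_equal(localization_error(m, e[1], e[2]),
               geodesic_distance(m, e[1], e[2]))
  expect_true(is.na(localization_error(m, 1, NA_integer_)))
})

test_that("evaluation report summaries are consistent with per-item values", {
  set.seed(2)
  xt <- matrix(rnorm(30 * 8), 30, 8)
  xr <- xt + 0.1 * matrix(rnorm(240), 30, 8)
  rep_ <- evaluation_report(xr, xt)
  expect_equal(rep_$summary$re_mean, mean(rep_$spatial$re), tolerance = 1e-12)
  expect_equal(rep_$summary$re_sd, sd(rep_$spatial$re), tolerance = 1e-12)
  expect_equal(rep_$summary$cc_mean, mean(rep_$spatial$cc), tolerance = 1e-12)
  expect_true(all(rep_$spatial$re >= 0))
  expect_true(all(abs(rep_$spatial$cc) <= 1))
  # RE_d column appears when the transfer system is supplied
  s <- random_system(1, m = 30, n = 30)
  rep2 <- evaluation_report(xr, xt, A = diag(30), b = xt)
  expect_true("re_d" %in% names(rep2$spatial))
  # inactive frames are excluded from the summary means
  xt2 <- xt; xt2[, 1] <- 1e-6 * xt2[, 1]
  rep3 <- evaluation_report(xr, xt2, min_ref_frac = 0.05)
  expect_false(rep3$spatial$active[1])
  expect_equal(rep3$summary$re_mean, mean(rep3$spatial$re[-1]),
               tolerance = 1e-12)
})
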