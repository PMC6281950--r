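test_that("analytic annulus solution satisfies its boundary conditions", {
  # l = 0: constant solution, zero radial derivative
  or0 <- analytic_annulus_forward(0, 0, 1, 2)
  pts <- icosphere(1.5, 0)$vertices
  expect_equal(or0$u(pts), rep(or0$u(pts)[1], nrow(pts)))
  expect_equal(or0$radial(1.3), 1)
  expect_equal(or0$dradial(1.7), 0)
  for (l in 1:5) {
    or <- analytic_annulus_forward(l, 0, 1, 2)
    expect_equal(or$radial(1), 1, tolerance = 1e-12)     # Dirichlet at r = a
    expect_equal(or$dradial(2), 0, tolerance = 1e-12)    # insulated at r = b
  }
})

test_that("annulus attenuation matches an independent 2x2 linear solve", {
  # independently solve [a^l, a^-(l+1); l b^(l-1), -(l+1) b^-(l+2)] (A,B) = (1,0)
  for (l in c(1, 3)) {
    a <- 1; b_out <- 2
    M <- rbind(c(a^l, a^(-(l + 1))),
               c(l * b_out^(l - 1), -(l + 1) * b_out^(-(l + 2))))
    AB <- solve(M, c(1, 0))
    or <- analytic_annulus_forward(l, 0, a, b_out)
    expect_equal(or$A_l, AB[1], tolerance = 1e-12)
    expect_equal(or$B_l, AB[2], tolerance = 1e-12)
    expect_equal(or$radial(b_out), AB[1] * b_out^l + AB[2] * b_out^(-(l + 1)),
                 tolerance = 1e-12)
  }
})

test_that("spherical harmonic basis is orthonormal and matches closed forms", {
  h <- icosphere(1, 2)
  Y <- sph_harm_basis(h$vertices, 3)
  expect_equal(Y[, 1], rep(1 / sqrt(4 * pi), 162))
  expect_equal(Y[, 3], sqrt(3 / (4 * pi)) * h$vertices[, 3])
  # discrete near-orthonormality on a quasi-uniform sphere sampling
  G <- crossprod(Y) * (4 * pi / 162)
  expect_lt(max(abs(G - diag(16))), 0.06)
})

test_that("MFS kernel rows and right-hand side have the documented structure", {
  p <- small_pair()
  sys <- build_mfs_transfer(p$heart, p$torso, source_stride = 2)
  ne <- sys$n_dirichlet; nt <- sys$n_neumann
  expect_equal(sys$m, ne + nt)
  expect_true(all(sys$A[seq_len(ne), 1] == 1))      # constant column, Dirichlet
  expect_true(all(sys$A[ne + seq_len(nt), 1] == 0)) # constant column, Neumann
  # Dirichlet entries are the kernel 1/(4 pi r)
  r <- sqrt(sum((p$torso$vertices[1, ] - sys$sources[1, ])^2))
  expect_equal(sys$A[1, 2], 1 / (4 * pi * r), tolerance = 1e-12)
  # b = [BSP; 0]
  bsp <- matrix(seq_len(nt), nt, 1)
  rhs <- mfs_rhs(sys, bsp)
  expect_equal(drop(rhs), c(bsp[sys$electrodes, 1], rep(0, nt)))
  # source coincidence
  expect_error(build_mfs_transfer(p$heart, p$torso, inflation = 1 + 1e-16),
               "inflation")
})

test_that("MFS coefficient-to-epicardium map matches the kernel definition", {
  p <- small_pair()
  sys <- build_mfs_transfer(p$heart, p$torso, source_stride = 2)
  ns <- nrow(sys$sources)
  expect_equal(mfs_reconstruct_epicardial(sys, rep(0, ns + 1)),
               rep(0, 42))
  expect_equal(mfs_reconstruct_epicardial(sys, c(3, rep(0, ns))),
               rep(3, 42))
  coef <- c(0, 1, rep(0, ns - 1))
  r1 <- sqrt(sum((p$heart$vertices[5, ] - sys$sources[1, ])^2))
  expect_equal(mfs_reconstruct_epicardial(sys, coef)[5],
               1 / (4 * pi * r1), tolerance = 1e-12)
  expect_error(mfs_reconstruct_epicardial(sys, rep(0, ns)), "length")
})

test_that("forward maps agree with the annulus oracle and respect constants", {
  p <- default_pair()
  sys <- default_fem()
  expect_lt(max(abs(sys$A %*% rep(1, 162) - 1)), 1e-6)   # l = 0 harmonic
  for (l in 1:3) {
    x <- harmonic_pattern(p$heart, l, 0)
    bt <- analytic_annulus_forward(l, 0, 1, 2)$u(p$torso$vertices)
    expect_lt(relative_error(drop(sys$A %*% x), bt), 0.02)
    expect_lt(relative_error(mfs_forward_solve(p$heart, p$torso, x), bt),
              0.01)
  }
  # full column rank on phantoms
  expect_gt(min(svd(sys$A)$d), 0)
})

test_that("FEM transfer rejects a heart outside the torso", {
  p <- small_pair()
  expect_error(build_fem_transfer(p$torso, p$heart), "inside")
})

test_that("Dirichlet-to-Neumann operator annihilates constants and matches
           analytic radial derivatives", {
  dtn <- default_dtn()
  p <- default_pair()
  expect_lt(max(abs(dtn$D %*% rep(1, 162))) / max(abs(dtn$D)), 1e-8)
  for (l in 1:3) {
    x <- harmonic_pattern(p$heart, l, 0)
    dn <- analytic_annulus_forward(l, 0, 1, 2)$dudr(p$heart$vertices)
    expect_lt(relative_error(drop(dtn$D %*% x), dn), if (l < 3) 0.05 else 0.08)
  }
})

test_that("DtN discrepancy against the analytic derivative shrinks with
           refinement", {
  p <- small_pair()
  x <- harmonic_pattern(p$heart, 2, 0)
  dn <- analytic_annulus_forward(2, 0, 1, 2)$dudr(p$heart$vertices)
  err <- vapply(c(2, 8), function(ref) {
    D <- build_dtn_operator(p$heart, p$torso, refinement = ref)$D
    relative_error(drop(D %*% x), dn)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("transfer systems reject underdetermined or non-finite setups", {
  p <- small_pair()
  expect_error(new_transfer_system(matrix(1, 2, 3), "fem", p$heart, p$torso),
               "underdetermined")
  expect_error(new_transfer_system(matrix(NaN, 3, 2), "fem", p$heart, p$torso),
               "non-finite")
})
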