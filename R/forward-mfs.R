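#' @rdname build_mfs_transfer
#' @export
new_transfer_system <- function(A, method, heart, torso, extra = list()) {
  m <- nrow(A); n <- ncol(A)
  if (m < n)
    stop("transfer system underdetermined: m = ", m, " rows < n = ", n,
         " unknowns")
  if (any(!is.finite(A))) stop("non-finite entries in transfer matrix")
  structure(c(list(A = A, method = method, m = m, n = n,
                   heart = heart, torso = torso), extra),
            class = "transfer_system")
}

#' @export
print.transfer_system <- function(x, ...) {
  cat(sprintf("<transfer_system %s: %d x %d>\n", x$method, x$m, x$n))
  invisible(x)
}

#' Method-of-fundamental-solutions transfer system
#'
#' Expands the torso potential in Laplace fundamental solutions
#' \eqn{f(r) = 1/(4\pi r)} anchored at fictitious source points outside the
#' solution domain: torso vertices inflated by `inflation` and heart vertices
#' deflated by `deflation` about the heart centroid. The unknowns are a
#' constant term plus one coefficient per source. Rows of `A` are Dirichlet
#' rows (kernel values at the body-surface electrodes, first column 1)
#' followed by Neumann rows (kernel normal derivatives at all torso vertices,
#' first column 0) expressing the insulated-torso condition; the matching
#' right-hand side is the concatenation of the measured body-surface
#' potentials and a zero block ([mfs_rhs()]).
#'
#' With equally sized phantom surfaces, using every vertex of both surfaces
#' as a source would leave the system underdetermined; `source_stride`
#' decimates the source sets (stride 2 halves them), mirroring the usual
#' MFS practice of fewer sources than measurements.
#'
#' @param heart,torso [surface_mesh()] objects.
#' @param electrodes torso vertex indices carrying potential measurements
#'   (default: all torso vertices).
#' @param inflation torso source inflation ratio (> 1; default 2, keeping
#'   the fictitious boundary well clear of the collocation surface — sources
#'   placed too close produce near-field ripple in the kernel expansion).
#' @param deflation heart source deflation ratio (in (0,1); default 0.5).
#' @param source_stride keep every `source_stride`-th vertex as a source.
#' @return a `transfer_system` with `method = "mfs"`; unknowns are
#'   `c(a0, a_1, ..., a_ns)`.
#' @export
build_mfs_transfer <- function(heart, torso, electrodes = NULL,
                               inflation = 2, deflation = 0.5,
                               source_stride = 1L) {
  if (!(inflation > 1)) stop("inflation ratio must be > 1")
  if (!(deflation > 0 && deflation < 1)) stop("deflation ratio must be in (0,1)")
  nt <- nrow(torso$vertices)
  if (is.null(electrodes)) electrodes <- seq_len(nt)
  stopifnot(all(electrodes >= 1), all(electrodes <= nt))
  src <- mfs_source_points(heart, torso, inflation, deflation, source_stride)
  ep <- torso$vertices[electrodes, , drop = FALSE]
  Kd <- mfs_kernel(ep, src)
  Kn <- mfs_kernel_dn(torso$vertices, torso$vertex_normals, src)
  A <- rbind(cbind(1, Kd), cbind(0, Kn))
  new_transfer_system(
    A, method = "mfs", heart = heart, torso = torso,
    extra = list(sources = src, electrodes = electrodes,
                 n_dirichlet = length(electrodes), n_neumann = nt,
                 inflation = inflation, deflation = deflation))
}

mfs_source_points <- function(heart, torso, inflation, deflation, stride = 1L) {
  ctr <- colMeans(heart$vertices)
  sub <- function(v) v[seq(1L, nrow(v), by = as.integer(stride)), , drop = FALSE]
  infl <- sweep(sweep(sub(torso$vertices), 2, ctr, "-") * inflation, 2, ctr, "+")
  defl <- sweep(sweep(sub(heart$vertices), 2, ctr, "-") * deflation, 2, ctr, "+")
  rbind(infl, defl)
}

# kernel matrix f(|x - y|) = 1/(4 pi |x - y|), rows = points, cols = sources
mfs_kernel <- function(points, sources) {
  d <- pair_dist(points, sources)
  if (any(d < 1e-12))
    stop("MFS source point coincides with an evaluation point")
  1 / (4 * pi * d)
}

# normal derivative of the kernel at the evaluation points:
# d/dn 1/(4 pi |x-y|) = -(x-y).n / (4 pi |x-y|^3)
mfs_kernel_dn <- function(points, normals, sources) {
  d <- pair_dist(points, sources)
  if (any(d < 1e-12))
    stop("MFS source point coincides with an evaluation point")
  num <- outer(rowSums(points * normals), rep(1, nrow(sources))) -
    tcrossprod(normals, sources)
  -num / (4 * pi * d^3)
}

pair_dist <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(Y))) +
    outer(rep(1, nrow(X)), rowSums(Y^2)) - 2 * tcrossprod(X, Y)
  sqrt(pmax(d2, 0))
}

#' Right-hand side for a transfer system
#'
#' For FEM the right-hand side is the body-surface potential frame itself;
#' for MFS it is the concatenation of the electrode potentials and a zero
#' block of one row per insulated-torso flux constraint.
#'
#' @param system a `transfer_system`.
#' @param bsp body-surface potentials: vector over torso vertices, or a
#'   matrix (torso vertices x frames).
#' @return vector or matrix with `system$m` rows.
#' @export
mfs_rhs <- function(system, bsp) {
  bsp <- as.matrix(bsp)
  if (system$method == "fem") return(bsp)
  z <- matrix(0, system$n_neumann, ncol(bsp))
  rbind(bsp[system$electrodes, , drop = FALSE], z)
}

#' Epicardial potentials from MFS coefficients
#'
#' \eqn{u_H(p) = a_0 + \sum_j a_j / (4\pi \|p - y_j\|)} evaluated at the
#' heart vertices.
#'
#' @param system an MFS `transfer_system`.
#' @param coefficients solution vector `c(a0, a_1, ..., a_ns)`.
#' @return numeric vector (or matrix for multi-frame input) of epicardial
#'   potentials.
#' @export
mfs_reconstruct_epicardial <- function(system, coefficients) {
  stopifnot(system$method == "mfs")
  coefficients <- as.matrix(coefficients)
  if (nrow(coefficients) != nrow(system$sources) + 1L)
    stop("coefficient length must be number of sources + 1")
  K <- mfs_kernel(system$heart$vertices, system$sources)
  out <- sweep(K %*% coefficients[-1L, , drop = FALSE], 2,
               coefficients[1L, ], "+")
  if (ncol(out) == 1L) drop(out) else out
}

#' Map a transfer-system solution to epicardial potentials
#' @param system a `transfer_system`.
#' @param x solution vector/matrix in the system's unknowns.
#' @return epicardial potentials at heart vertices.
#' @export
epicardial_potentials <- function(system, x) {
  if (system$method == "mfs") mfs_reconstruct_epicardial(system, x)
  else if (is.matrix(x) && ncol(x) == 1L) drop(x) else x
}

#' MFS forward solve on a two-surface phantom
#'
#' Solves the forward problem by least squares: coefficients are fitted to
#' match given epicardial Dirichlet data at the heart vertices and zero
#' normal flux at the torso vertices, and the potential is then evaluated at
#' the torso vertices. Used to validate the MFS discretization against the
#' analytic annulus oracle.
#'
#' @inheritParams build_mfs_transfer
#' @param x_h epicardial potentials at heart vertices.
#' @return torso-surface potentials.
#' @export
mfs_forward_solve <- function(heart, torso, x_h, inflation = 2,
                              deflation = 0.5, source_stride = 1L) {
  src <- mfs_source_points(heart, torso, inflation, deflation, source_stride)
  Ad <- cbind(1, mfs_kernel(heart$vertices, src))
  An <- cbind(0, mfs_kernel_dn(torso$vertices, torso$vertex_normals, src))
  # truncated-SVD least squares: tolerant of rank deficiency in the
  # (often nearly singular) collocation matrix
  M <- rbind(Ad, An)
  rhs <- c(x_h, numeric(nrow(torso$vertices)))
  s <- svd(M)
  keep <- s$d > 1e-12 * s$d[1]
  coef <- s$v[, keep, drop = FALSE] %*%
    (crossprod(s$u[, keep, drop = FALSE], rhs) / s$d[keep])
  drop(cbind(1, mfs_kernel(torso$vertices, src)) %*% coef)
}
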