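#' Real spherical-harmonic basis at points
#'
#' Evaluates the real orthonormal spherical harmonics \eqn{Y_{lm}} (degree
#' `l`, order `m = -l..l`) at the directions of the given points. Associated
#' Legendre functions come from [pracma::legendre()] (MATLAB convention,
#' Condon-Shortley phase included); normalization makes the basis orthonormal
#' on the unit sphere.
#'
#' @param points matrix of 3D points (rows); only directions are used.
#' @param lmax maximum degree.
#' @return matrix with `nrow(points)` rows and `(lmax+1)^2` columns, ordered
#'   by degree then order (`m = -l, ..., l`).
#' @export
sph_harm_basis <- function(points, lmax) {
  points <- matrix(points, ncol = 3)
  r <- sqrt(rowSums(points^2))
  ct <- points[, 3] / r
  ct <- pmin(1, pmax(-1, ct))
  phi <- atan2(points[, 2], points[, 1])
  np <- nrow(points)
  out <- matrix(0, np, (lmax + 1)^2)
  col <- 0L
  for (l in 0:lmax) {
    P <- pracma::legendre(l, ct)             # (l+1) x np, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    for (m in (-l):l) {
      col <- col + 1L
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      Pl <- P[am + 1L, ]
      out[, col] <-
        if (m == 0) nrm * Pl
        else if (m > 0) sqrt(2) * nrm * Pl * cos(am * phi)
        else sqrt(2) * nrm * Pl * sin(am * phi)
    }
  }
  out
}

#' Analytic Laplace solution on a concentric spherical annulus
#'
#' Closed-form solution of the volume-conductor problem on the annulus
#' `a < r < b_out` with Dirichlet data \eqn{Y_{lm}} on the inner (heart)
#' sphere and an insulated outer (torso) sphere:
#' \deqn{u = (A_l r^l + B_l r^{-(l+1)}) Y_{lm},}
#' with \eqn{B_l = A_l\, l\, b^{2l+1}/(l+1)} (zero flux at `r = b_out`) and
#' \eqn{A_l a^l + B_l a^{-(l+1)} = 1} (unit Dirichlet data at `r = a`).
#' Serves as the independent forward oracle against which the FEM and MFS
#' discrete transfer operators are validated, and as the phantom generator's
#' forward map (avoiding the inverse crime).
#'
#' @param l harmonic degree (>= 0).
#' @param m harmonic order, `|m| <= l`.
#' @param a inner radius.
#' @param b_out outer radius (> a).
#' @return a list with coefficients `A_l`, `B_l`, `radial(r)` and
#'   `dradial(r)` (the radial profile and its derivative, profile = 1 at
#'   `r = a`), and evaluators `u(points)`, `dudr(points)`.
#' @export
analytic_annulus_forward <- function(l, m = 0, a = 1, b_out = 2) {
  stopifnot(l >= 0, abs(m) <= l, a > 0, b_out > a)
  if (l == 0) {
    A <- 1; B <- 0
  } else {
    # B = A * l b^(2l+1) / (l+1);  A a^l + B a^-(l+1) = 1
    k <- l * b_out^(2 * l + 1) / (l + 1)
    A <- 1 / (a^l + k * a^(-(l + 1)))
    B <- A * k
  }
  radial <- function(r) A * r^l + B * r^(-(l + 1))
  dradial <- function(r) l * A * r^(l - 1) - (l + 1) * B * r^(-(l + 2))
  ylm <- function(points) {
    Y <- sph_harm_basis(points, l)
    Y[, l^2 + l + m + 1L]
  }
  list(
    A_l = A, B_l = B, radial = radial, dradial = dradial,
    u = function(points) {
      points <- matrix(points, ncol = 3)
      radial(sqrt(rowSums(points^2))) * ylm(points)
    },
    dudr = function(points) {
      points <- matrix(points, ncol = 3)
      dradial(sqrt(rowSums(points^2))) * ylm(points)
    })
}

#' Analytic forward transfer matrix for concentric-sphere phantoms
#'
#' Builds the oracle forward map from inner-sphere (epicardial) vertex
#' potentials to outer-sphere (torso) vertex potentials by projecting onto
#' spherical harmonics up to `lmax` (least squares at the heart vertices),
#' attenuating each degree with the analytic annulus profile, and evaluating
#' at the torso vertices. Independent of the FEM/MFS operators under test.
#'
#' @param heart,torso concentric-sphere [surface_mesh()] objects.
#' @param lmax truncation degree of the harmonic expansion; `(lmax+1)^2`
#'   must not exceed the heart vertex count.
#' @return dense matrix (torso vertices x heart vertices).
#' @export
oracle_forward_matrix <- function(heart, torso, lmax = 8) {
  rh <- sqrt(rowSums(heart$vertices^2))
  rt <- sqrt(rowSums(torso$vertices^2))
  if (diff(range(rh)) > 1e-8 * mean(rh) || diff(range(rt)) > 1e-8 * mean(rt))
    stop("oracle_forward_matrix requires concentric spherical meshes")
  a <- mean(rh); b <- mean(rt)
  K <- (lmax + 1)^2
  if (K > nrow(heart$vertices))
    stop("harmonic basis larger than heart vertex count")
  Yh <- sph_harm_basis(heart$vertices, lmax)
  Yt <- sph_harm_basis(torso$vertices, lmax)
  att <- unlist(lapply(0:lmax, function(l) {
    rep(analytic_annulus_forward(l, 0, a, b)$radial(b), 2 * l + 1)
  }))
  proj <- solve(crossprod(Yh), t(Yh))         # harmonic coefficients from values
  Yt %*% (att * proj)
}
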