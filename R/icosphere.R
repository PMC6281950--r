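#' Geodesic icosahedral sphere
#'
#' Recursive 4-way subdivision of the icosahedron with projection to the
#' sphere. Vertex count is `10 * 4^s + 2`; the vertex order is stable, and the
#' vertices of subdivision level `s-1` appear first in level `s`, so pacing
#' sites chosen on a coarse sphere remain valid on refinements.
#'
#' @param radius sphere radius (> 0, any consistent length unit).
#' @param subdivisions integer >= 0 subdivision depth.
#' @param role mesh role, `"heart"` or `"torso"`.
#' @return a [surface_mesh()].
#' @examples
#' m <- icosphere(1, 1)
#' nrow(m$vertices)  # 42
#' @export
icosphere <- function(radius = 1, subdivisions = 0L, role = c("heart", "torso")) {
  role <- match.arg(role)
  stopifnot(radius > 0, subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  s <- 0L
  while (s < subdivisions) {
    res <- subdivide_once(v, f)
    v <- res$v; f <- res$f
    s <- s + 1L
  }
  surface_mesh(v * radius, f, role = role)
}

subdivide_once <- function(v, f) {
  nv <- nrow(v)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ue <- unique(e)
  key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
  mid_index <- structure(nv + seq_len(nrow(ue)), names = key(ue[, 1], ue[, 2]))
  mid <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  m12 <- mid_index[as.character(key(f[, 1], f[, 2]))]
  m23 <- mid_index[as.character(key(f[, 2], f[, 3]))]
  m31 <- mid_index[as.character(key(f[, 3], f[, 1]))]
  f2 <- rbind(cbind(f[, 1], m12, m31),
              cbind(f[, 2], m23, m12),
              cbind(f[, 3], m31, m23),
              cbind(m12, m23, m31))
  list(v = rbind(v, mid), f = unname(f2))
}
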