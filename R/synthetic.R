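#' Spherical-harmonic epicardial test pattern
#'
#' `amplitude * Y_lm` evaluated at the heart vertices; the patterns the
#' analytic annulus oracle propagates exactly, used for forward-model
#' validation and round-trip tests.
#'
#' @param heart heart [surface_mesh()].
#' @param l degree (>= 0).
#' @param m order, `|m| <= l`.
#' @param amplitude scale factor (mV).
#' @return numeric vector over heart vertices.
#' @export
harmonic_pattern <- function(heart, l, m = 0, amplitude = 1) {
  stopifnot(l >= 0, abs(m) <= l)
  Y <- sph_harm_basis(heart$vertices, l)
  amplitude * Y[, l^2 + l + m + 1L]
}

#' Paced-wavefront epicardial potential time series
#'
#' A stimulus at `pacing_vertex` propagates along the surface at constant
#' `speed`; vertex `v` activates at `t_act(v) = geodesic(pacing, v)/speed`
#' (frames) and its potential follows a logistic step from `resting_mv` to
#' `plateau_mv` of temporal width `transition_width`, with the step midpoint
#' delayed by two widths after `t_act` so that at frame 0 only the pacing
#' vertex has begun its transition. The moving front carries the sharp
#' spatial potential leap the L1 current-density scheme is designed to
#' preserve.
#'
#' Defaults follow the extracellular unipolar convention — the quantity an
#' ECGI pipeline actually reconstructs: baseline (resting) potential 0 mV
#' and a negative-going activated plateau (-40 mV), so the
#' earliest-activated region is the spatial minimum, consistent with
#' [detect_pacing_site()]'s default rule.
#'
#' @param heart heart [surface_mesh()].
#' @param pacing_vertex stimulated vertex index.
#' @param speed conduction speed in length units per frame (> 0).
#' @param frames number of time frames (>= 2).
#' @param resting_mv resting (baseline) potential level (default 0).
#' @param plateau_mv activated plateau level (default -40).
#' @param transition_width temporal width of the upstroke in frames
#'   (default 2).
#' @return matrix (heart vertices x frames) with attributes
#'   `activation_time` (frames, per vertex) and `pacing_vertex`.
#' @export
paced_wave <- function(heart, pacing_vertex, speed = 0.06, frames = 60L,
                       resting_mv = 0, plateau_mv = -40,
                       transition_width = 2) {
  stopifnot(speed > 0, frames >= 2)
  d <- geodesic_distance(heart, pacing_vertex)
  t_act <- d / speed
  tt <- seq_len(frames) - 1
  X <- vapply(tt, function(t)
    resting_mv + (plateau_mv - resting_mv) *
      stats::plogis((t - t_act - 2 * transition_width) / transition_width),
    numeric(length(t_act)))
  attr(X, "activation_time") <- t_act
  attr(X, "pacing_vertex") <- pacing_vertex
  X
}

#' Additive Gaussian measurement noise at a prescribed SNR
#'
#' Zero-mean Gaussian noise scaled so that the realized signal-to-noise
#' ratio `20 log10(||B|| / ||noise||)` equals `snr_db` exactly.
#' Reproducible under `seed`; `snr_db = Inf` returns the input unchanged.
#'
#' @param b_clean clean data matrix (electrodes x frames) or vector.
#' @param snr_db target SNR in dB.
#' @param seed RNG seed.
#' @return noisy data of the same shape.
#' @export
add_noise <- function(b_clean, snr_db, seed = 1L) {
  if (!is.finite(snr_db)) return(b_clean)
  B <- as.matrix(b_clean)
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  N <- matrix(stats::rnorm(length(B)), nrow(B), ncol(B))
  N <- N * sqrt(sum(B^2)) / sqrt(sum(N^2)) * 10^(-snr_db / 20)
  out <- B + N
  if (is.null(dim(b_clean))) drop(out) else out
}

#' Synthetic heart-torso phantom dataset
#'
#' Generates the complete study object every inverse pipeline stage is
#' exercised on: concentric-sphere heart and torso meshes, a paced-wavefront
#' ground-truth epicardial potential series, clean body-surface potentials
#' produced by the analytic annulus forward oracle (an operator independent
#' of the FEM/MFS matrices under test — the guard against the inverse
#' crime), and noisy measurements at the requested SNR.
#'
#' @param heart_radius,torso_radius sphere radii (default 1 and 2 length
#'   units).
#' @param subdivisions icosphere subdivision depth (default 2: 162 vertices
#'   per surface).
#' @param frames number of time frames (default 60).
#' @param pacing_vertex stimulated heart vertex (default 1).
#' @param speed conduction speed, length units per frame.
#' @param snr_db measurement SNR in dB (default 20; `Inf` for noise-free).
#' @param seed RNG seed for the noise.
#' @param oracle_lmax harmonic band of the oracle forward map (default 10).
#'   The stored ground truth is the band-limited (degree `<= oracle_lmax`)
#'   projection of the logistic wave: the 162-vertex sphere cannot represent
#'   higher degrees anyway, and band-limiting makes the analytic forward
#'   exact for the stored truth while remaining independent of the FEM/MFS
#'   operators under test.
#' @param ... further arguments passed to [paced_wave()].
#' @return a `phantom_dataset` list: `heart`, `torso`, `x_true`, `b_clean`,
#'   `b_noisy`, `a_oracle`, `pacing_vertex`, `speed`, `snr_db`, `seed`,
#'   `polarity` (`"min"`: the activated region is negative-going).
#' @export
phantom_dataset <- function(heart_radius = 1, torso_radius = 2,
                            subdivisions = 2L, frames = 60L,
                            pacing_vertex = 1L, speed = 0.06, snr_db = 20,
                            seed = 1L, oracle_lmax = 10L, ...) {
  heart <- icosphere(heart_radius, subdivisions, role = "heart")
  torso <- icosphere(torso_radius, subdivisions, role = "torso")
  X <- paced_wave(heart, pacing_vertex, speed = speed, frames = frames, ...)
  tact <- attr(X, "activation_time")
  # the basis cannot exceed what the mesh supports
  oracle_lmax <- min(oracle_lmax,
                     floor(sqrt(nrow(heart$vertices))) - 1L)
  # band-limit the stored truth to the oracle's harmonic band
  Yh <- sph_harm_basis(heart$vertices, oracle_lmax)
  X <- Yh %*% solve(crossprod(Yh), crossprod(Yh, X))
  attr(X, "activation_time") <- tact
  attr(X, "pacing_vertex") <- pacing_vertex
  A_or <- oracle_forward_matrix(heart, torso, lmax = oracle_lmax)
  B_clean <- A_or %*% X
  B_noisy <- add_noise(B_clean, snr_db, seed)
  structure(list(heart = heart, torso = torso, x_true = X,
                 b_clean = B_clean, b_noisy = B_noisy, a_oracle = A_or,
                 pacing_vertex = pacing_vertex, speed = speed,
                 snr_db = snr_db, seed = seed, polarity = "min"),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf(
    "<phantom_dataset: %d heart / %d torso vertices, %d frames, SNR %s dB, pacing vertex %d>\n",
    nrow(x$heart$vertices), nrow(x$torso$vertices), ncol(x$x_true),
    format(x$snr_db), x$pacing_vertex))
  invisible(x)
}

#' Two-level (step) epicardial pattern
#'
#' A spherical-cap step: vertices within `cap_angle` geodesic radius of
#' `center_vertex` sit at the activated level `active_mv`, the rest at the
#' baseline `rest_mv`, with a narrow smoothed edge. The spatial
#' discontinuity is the feature L1 current-density regularization preserves
#' better than zero-order Tikhonov.
#'
#' @param heart heart [surface_mesh()].
#' @param center_vertex cap center vertex.
#' @param cap_angle geodesic cap radius (length units, default 1).
#' @param active_mv,rest_mv the two levels (defaults -40 and 0).
#' @param edge_width smoothing width of the cap edge (default 0.1).
#' @return numeric vector over heart vertices.
#' @export
step_pattern <- function(heart, center_vertex = 1L, cap_angle = 1,
                         active_mv = -40, rest_mv = 0, edge_width = 0.1) {
  d <- geodesic_distance(heart, center_vertex)
  rest_mv + (active_mv - rest_mv) * stats::plogis((cap_angle - d) / edge_width)
}

#' Write a phantom dataset to plain-text files
#'
#' Meshes as OFF, potentials as tab-separated matrices, and a JSON manifest
#' (seed, SNR, pacing vertex, speed, polarity).
#'
#' @param phantom a [phantom_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mesh(phantom$heart, file.path(dir, "heart.off"))
  write_mesh(phantom$torso, file.path(dir, "torso.off"))
  utils::write.table(phantom$x_true, file.path(dir, "x_true.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(phantom$b_noisy, file.path(dir, "b_noisy.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(phantom$b_clean, file.path(dir, "b_clean.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  manifest <- list(seed = phantom$seed, snr_db = phantom$snr_db,
                   pacing_vertex = phantom$pacing_vertex,
                   speed = phantom$speed, polarity = phantom$polarity)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
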