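# Fixtures built in code: tiny postures and datasets for camera and
# evaluation tests.

# A bare posture of ground-plane landmarks (z = 0) with no primitives;
# bypasses the kinematic chain for pure projection tests.
planar_posture <- function(xy, labels = paste0("p", seq_len(nrow(xy)))) {
  structure(list(
    landmarks = tibble::tibble(landmark = labels,
                               x = xy[, 1], y = xy[, 2], z = 0),
    primitives = tibble::tibble(type = character(), x1 = numeric(),
                                y1 = numeric(), z1 = numeric(),
                                x2 = numeric(), y2 = numeric(),
                                z2 = numeric(), radius = numeric(),
                                part = character()),
    scale = 1), class = "posture3d")
}

# A posture holding a single sphere primitive (and a landmark at its centre).
sphere_posture <- function(center, radius) {
  structure(list(
    landmarks = tibble::tibble(landmark = "c", x = center[1], y = center[2],
                               z = center[3]),
    primitives = tibble::tibble(type = "sphere", x1 = center[1],
                                y1 = center[2], z1 = center[3],
                                x2 = 0, y2 = 0, z2 = 0, radius = radius,
                                part = "s"),
    scale = 1), class = "posture3d")
}

# Random annotation tibble for round-trip tests.
random_annotations <- function(n_frames, n_landmarks, seed) {
  set.seed(seed)
  labels <- paste0("lm", seq_len(n_landmarks))
  tidyr::expand_grid(frame = seq_len(n_frames), landmark = labels) |>
    dplyr::mutate(x = round(runif(dplyr::n(), 0, 640), 6),
                  y = round(runif(dplyr::n(), 0, 480), 6),
                  visible = runif(dplyr::n()) > 0.2)
}

# Ground-truth tibble with m frames of the full 22-landmark set.
synthetic_truth <- function(n_frames, seed = 1) {
  set.seed(seed)
  tidyr::expand_grid(frame = seq_len(n_frames),
                     landmark = landmark_names()) |>
    dplyr::mutate(x = runif(dplyr::n(), 50, 590),
                  y = runif(dplyr::n(), 50, 430),
                  visible = TRUE)
}

# Exact two-sided signed-rank p by exhaustive sign enumeration (no ties,
# no zeros assumed).
signed_rank_exact_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  min(p, 1)
}

# Friedman chi-square from first principles (within-row ranks, no ties).
friedman_statistic_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- colSums(t(apply(m, 1, rank)))
  12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
}
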