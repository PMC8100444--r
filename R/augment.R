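#' Ranges for random frame transformations
#'
#' The three geometric augmentations applied per frame: translation (T) of
#' the animal in the image plane, rotation (R) of the camera about its
#' viewing axis, and scaling (S) of all body segment lengths. Defaults are
#' the study ranges: translation uniform over `[-30, 30]` px in either
#' direction, rotation uniform over `[0, 2*pi)` rad, and scale drawn
#' uniformly from \{0.5, 0.7, 1.0, 1.3, 1.5\}.
#'
#' @param translate,rotate,scale enable flags for each component.
#' @param translation_bound half-width of the translation square (px).
#' @param rotation_support either `"uniform"` (continuous over
#'   `[0, 2*pi)`) or a numeric vector of discrete rotation angles (rad).
#' @param scale_support numeric vector of admissible scale factors.
#' @return A list of class `transform_ranges`.
#' @export
transform_ranges <- function(translate = FALSE, rotate = FALSE, scale = FALSE,
                             translation_bound = 30,
                             rotation_support = "uniform",
                             scale_support = c(0.5, 0.7, 1.0, 1.3, 1.5)) {
  if (translate && translation_bound <= 0)
    rlang::abort("translation enabled but bound is not positive")
  if (rotate && is.numeric(rotation_support) && !length(rotation_support))
    rlang::abort("rotation enabled but its support is empty")
  if (scale && (!length(scale_support) || any(scale_support <= 0)))
    rlang::abort("scale enabled but its support is empty or non-positive")
  structure(list(translate = translate, rotate = rotate, scale = scale,
                 translation_bound = translation_bound,
                 rotation_support = rotation_support,
                 scale_support = scale_support),
            class = "transform_ranges")
}

#' Draw per-frame transformations
#'
#' Samples `n` independent transformation triples from the enabled
#' supports using the current RNG state (seed at the call site for
#' reproducibility). Disabled components return identity values
#' (0 px, 0 rad, scale 1).
#'
#' @param n number of frames to draw for.
#' @param ranges a [transform_ranges()].
#' @return Tibble with `tx`, `ty` (px), `rotation` (rad), `scale`.
#' @export
sample_transforms <- function(n, ranges = transform_ranges()) {
  stopifnot(inherits(ranges, "transform_ranges"), n >= 0)
  n <- as.integer(n)
  tx <- ty <- rep(0, n)
  rot <- rep(0, n)
  sc <- rep(1, n)
  if (ranges$translate) {
    b <- ranges$translation_bound
    tx <- runif(n, -b, b)
    ty <- runif(n, -b, b)
  }
  if (ranges$rotate) {
    rot <- if (identical(ranges$rotation_support, "uniform")) {
      runif(n, 0, 2 * pi)
    } else {
      ranges$rotation_support[sample.int(length(ranges$rotation_support), n,
                                         replace = TRUE)]
    }
  }
  if (ranges$scale)
    sc <- ranges$scale_support[sample.int(length(ranges$scale_support), n,
                                          replace = TRUE)]
  tibble::tibble(tx = tx, ty = ty, rotation = rot, scale = sc)
}

#' @rdname sample_transforms
#' @return `sample_transform()` returns a single one-row tibble.
#' @export
sample_transform <- function(ranges = transform_ranges()) {
  sample_transforms(1L, ranges)
}

#' Apply one transformation triple to a posture and camera
#'
#' Scaling multiplies the posture's coordinates and radii about the world
#' origin (equivalent to scaling every segment length before forward
#' kinematics). Rotation is added to the camera roll. Translation moves
#' the camera's in-plane target so that ground-plane projections shift by
#' exactly the requested pixel amount. Ground truth is recomputed from the
#' returned pair, so annotations always match the rendered frame.
#'
#' @param posture a `posture3d`.
#' @param camera a [make_camera()].
#' @param spec one-row tibble with `tx`, `ty`, `rotation`, `scale` (as
#'   from [sample_transform()]).
#' @return List with transformed `posture` and `camera`.
#' @export
apply_transform <- function(posture, camera, spec) {
  stopifnot(inherits(posture, "posture3d"), inherits(camera, "camera_model"))
  spec <- as.list(spec)
  stopifnot(is.finite(spec$tx), is.finite(spec$ty),
            is.finite(spec$rotation), spec$scale > 0)
  s <- spec$scale
  if (s != 1) {
    posture$landmarks[c("x", "y", "z")] <- posture$landmarks[c("x", "y", "z")] * s
    posture$primitives[c("x1", "y1", "z1", "x2", "y2", "z2", "radius")] <-
      posture$primitives[c("x1", "y1", "z1", "x2", "y2", "z2", "radius")] * s
    posture$scale <- posture$scale * s
  }
  cam <- camera
  cam$roll <- camera$roll + spec$rotation
  d_cam <- c(spec$tx, -spec$ty) * camera$height / camera$f_px
  th <- -cam$roll
  Rinv <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cam$offset <- camera$offset - as.vector(Rinv %*% d_cam)
  list(posture = posture, camera = cam)
}
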