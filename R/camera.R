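#' Virtual top-view pinhole camera
#'
#' The camera hangs `height` world units above the ground plane looking
#' straight down. Its focal length in pixels is derived from the field of
#' view: with the default horizontal interpretation,
#' `f_px = (width / 2) / tan(fov / 2)`. `roll` rotates the camera about its
#' viewing axis (projections rotate by `-roll` about the image centre);
#' `offset` shifts the point on the ground the principal axis hits, in
#' world units. Pixel coordinates have their origin at the top-left image
#' corner, x rightward, y downward, pixel centres at integer + 0.5.
#'
#' @param width,height_px image size in pixels.
#' @param fov_deg field of view in degrees, in (0, 180).
#' @param height height of the camera above the ground plane (world units).
#' @param roll rotation about the viewing axis (rad).
#' @param offset length-2 in-plane offset of the principal-point target
#'   (world units).
#' @param fov_axis which image axis the field of view refers to:
#'   `"horizontal"` (default), `"vertical"` or `"diagonal"`.
#' @return An object of class `camera_model` with the derived `f_px`.
#' @export
make_camera <- function(width = 640, height_px = 480, fov_deg = 69.4,
                        height = 200, roll = 0, offset = c(0, 0),
                        fov_axis = c("horizontal", "vertical", "diagonal")) {
  fov_axis <- match.arg(fov_axis)
  if (width <= 0 || height_px <= 0)
    rlang::abort("image dimensions must be positive")
  if (fov_deg <= 0 || fov_deg >= 180)
    rlang::abort("field of view must lie strictly between 0 and 180 degrees")
  if (height <= 0) rlang::abort("camera height must be positive")
  if (length(offset) != 2L || !all(is.finite(offset)))
    rlang::abort("offset must be two finite numbers")
  half <- switch(fov_axis,
                 horizontal = width / 2,
                 vertical = height_px / 2,
                 diagonal = sqrt(width^2 + height_px^2) / 2)
  f_px <- half / tan(fov_deg / 2 * pi / 180)
  structure(list(width = as.integer(width), height_px = as.integer(height_px),
                 fov_deg = fov_deg, fov_axis = fov_axis, height = height,
                 roll = roll, offset = as.numeric(offset), f_px = f_px),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("<camera_model> ", x$width, "x", x$height_px, " px, fov ", x$fov_deg,
      " deg (", x$fov_axis, ", f = ", round(x$f_px, 2), " px), height ",
      x$height, ", roll ", round(x$roll, 4), " rad\n", sep = "")
  invisible(x)
}

# World -> camera-frame xy (roll applied, offset removed). z unchanged.
camera_frame_xy <- function(camera, xy) {
  th <- camera$roll
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(xy, 2, camera$offset) %*% t(R)
}

#' Project 3D world points to pixel coordinates
#'
#' Perspective projection through the camera. Points at or above the
#' camera plane (non-positive depth) are flagged invalid and get NA
#' coordinates.
#'
#' @param camera a [make_camera()].
#' @param points matrix or data frame with columns x, y, z (world units,
#'   ground plane z = 0).
#' @return Tibble with `x`, `y` (pixels), `depth` and `valid`.
#' @export
project_points <- function(camera, points) {
  stopifnot(inherits(camera, "camera_model"))
  pts <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  depth <- camera$height - pts[, 3]
  valid <- is.finite(depth) & depth > 0
  if (any(!valid))
    rlang::warn("some points lie at or behind the camera plane; flagged invalid")
  cc <- camera_frame_xy(camera, pts[, 1:2, drop = FALSE])
  u <- unname(camera$width / 2 + camera$f_px * cc[, 1] / depth)
  v <- unname(camera$height_px / 2 - camera$f_px * cc[, 2] / depth)
  u[!valid] <- NA_real_
  v[!valid] <- NA_real_
  tibble::tibble(x = u, y = v, depth = unname(depth), valid = unname(valid))
}

#' @rdname project_points
#' @param p a single 3D point (length-3 numeric).
#' @export
project_point <- function(camera, p) {
  project_points(camera, matrix(p, nrow = 1,
                                dimnames = list(NULL, c("x", "y", "z"))))
}

#' Convert a pixel error to millimetres
#'
#' @param error_px error in pixels (>= 0).
#' @param resolution ground-plane resolution in mm per pixel (> 0).
#' @return Error in millimetres (exact product).
#' @export
px_to_mm <- function(error_px, resolution) {
  if (any(resolution <= 0)) rlang::abort("resolution must be positive")
  error_px * resolution
}

#' Effective resolution at a body-scale factor
#'
#' Rendering the animal at scale `s` leaves the camera untouched, so a
#' smaller animal spans fewer pixels: the effective resolution is
#' `base_resolution / s` mm per pixel. The base resolution is a measured
#' constant of the rendering setup (default 0.28 mm/px at scale 1),
#' supplied rather than derived from the camera model.
#'
#' @param base_resolution mm per pixel at scale 1 (> 0).
#' @param s body scale factor (> 0).
#' @return mm per pixel at scale `s`.
#' @export
resolution_at_scale <- function(base_resolution = 0.28, s = 1) {
  if (any(base_resolution <= 0)) rlang::abort("base resolution must be positive")
  if (any(s <= 0)) rlang::abort("scale factor must be positive")
  base_resolution / s
}
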