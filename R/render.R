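#' Appearance settings for the ray-cast renderer
#'
#' The body is rendered as a smooth untextured gray surface on a uniform
#' background, lit by a single directional light from the camera with an
#' ambient floor. Values are model choices approximating a gray insect on
#' a lab arena floor.
#'
#' @param background background intensity (0-255).
#' @param body_gray peak body intensity (0-255).
#' @param ambient ambient fraction of the shading, in `[0, 1]`.
#' @return A list of class `appearance`.
#' @export
default_appearance <- function(background = 110, body_gray = 205,
                               ambient = 0.35) {
  stopifnot(background >= 0, background <= 255,
            body_gray >= 0, body_gray <= 255,
            ambient >= 0, ambient <= 1)
  structure(list(background = as.integer(background),
                 body_gray = as.integer(body_gray), ambient = ambient),
            class = "appearance")
}

# Primitive tibble -> matrix in the camera-aligned frame.
primitives_camera_frame <- function(posture, camera) {
  pr <- posture$primitives
  p1 <- camera_frame_xy(camera, as.matrix(pr[, c("x1", "y1")]))
  p2 <- camera_frame_xy(camera, as.matrix(pr[, c("x2", "y2")]))
  cbind(ifelse(pr$type == "cylinder", 1, 0),
        p1[, 1], p1[, 2], pr$z1, p2[, 1], p2[, 2], pr$z2, pr$radius)
}

#' Render a posture into a grayscale frame
#'
#' Analytic ray-casting of the posture's sphere and finite-cylinder
#' primitives: each pixel's ray is intersected with every primitive (via a
#' per-primitive screen bounding box), the nearest hit wins, and the
#' surface is shaded Lambertian-style from the camera direction.
#' Deterministic; no sampling involved.
#'
#' @param posture a `posture3d` (use [build_posture()] so tarsi and
#'   abdomen are included).
#' @param camera a [make_camera()].
#' @param appearance a [default_appearance()].
#' @return An integer matrix (`height_px` rows by `width` columns) of
#'   intensities in 0-255, class `stick_frame`.
#' @export
render_frame <- function(posture, camera = make_camera(),
                         appearance = default_appearance()) {
  stopifnot(inherits(posture, "posture3d"), inherits(camera, "camera_model"))
  prm <- primitives_camera_frame(posture, camera)
  img <- render_cpp(prm, camera$width, camera$height_px, camera$f_px,
                    camera$height, appearance$background,
                    appearance$body_gray, appearance$ambient)
  structure(img, class = c("stick_frame", class(img)))
}

#' @export
print.stick_frame <- function(x, ...) {
  cat("<stick_frame> ", nrow(x), "x", ncol(x), " px, intensities ",
      min(x), "-", max(x), "\n", sep = "")
  invisible(x)
}

# Which primitives contain (or touch) a given landmark point. These are
# the landmark's own body parts and are exempt from its occlusion test.
adjacent_primitives <- function(posture, point, tol = 1e-6) {
  pr <- posture$primitives
  hit <- logical(nrow(pr))
  for (i in seq_len(nrow(pr))) {
    r <- pr$radius[i] + tol
    if (pr$type[i] == "sphere") {
      hit[i] <- sum((point - c(pr$x1[i], pr$y1[i], pr$z1[i]))^2) <= r^2
    } else {
      a <- c(pr$x2[i], pr$y2[i], pr$z2[i]) - c(pr$x1[i], pr$y1[i], pr$z1[i])
      len <- sqrt(sum(a^2))
      if (len < tol) next
      a <- a / len
      w <- point - c(pr$x1[i], pr$y1[i], pr$z1[i])
      s <- sum(w * a)
      if (s < -tol || s > len + tol) next
      hit[i] <- sum((w - s * a)^2) <= r^2
    }
  }
  which(hit)
}

#' Landmark visibility under a camera
#'
#' A landmark is visible iff its projection falls inside the image and the
#' ray from the camera to the landmark meets no other body primitive
#' strictly nearer than the landmark itself. Primitives that contain the
#' landmark (its own joint sphere and the segments meeting there) are
#' exempt, so joints are not occluded by themselves.
#'
#' @param posture a `posture3d`.
#' @param camera a [make_camera()].
#' @param clearance tolerance (world units) subtracted from the landmark
#'   distance before comparing against the nearest hit.
#' @return Tibble with `landmark` and logical `visible`.
#' @export
compute_visibility <- function(posture, camera = make_camera(),
                               clearance = 1e-6) {
  stopifnot(inherits(posture, "posture3d"))
  lm <- posture$landmarks
  proj <- project_points(camera, lm)
  in_frame <- proj$valid & !is.na(proj$x) &
    proj$x >= 0 & proj$x <= camera$width &
    proj$y >= 0 & proj$y <= camera$height_px
  pts_cam <- cbind(camera_frame_xy(camera, as.matrix(lm[, c("x", "y")])),
                   lm$z)
  skip <- lapply(seq_len(nrow(lm)), function(i)
    as.integer(adjacent_primitives(posture,
                                   unlist(lm[i, c("x", "y", "z")]))))
  prm <- primitives_camera_frame(posture, camera)
  t_hit <- nearest_hit_cpp(prm, camera$height, pts_cam, skip)
  dist <- sqrt(pts_cam[, 1]^2 + pts_cam[, 2]^2 +
                 (camera$height - pts_cam[, 3])^2)
  tibble::tibble(landmark = lm$landmark,
                 visible = in_frame & (t_hit >= dist - clearance))
}

#' Write a rendered frame as an 8-bit grayscale PNG
#'
#' @param frame a `stick_frame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(unclass(frame) / 255, path)
  invisible(path)
}

#' Read a grayscale PNG back into a frame matrix
#' @param path PNG file written by [write_frame_png()].
#' @return Integer matrix of intensities 0-255, class `stick_frame`.
#' @export
read_frame_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  structure(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)),
            class = c("stick_frame", "matrix", "array"))
}

#' Plot a rendered frame, optionally with its annotations
#'
#' @param object a `stick_frame`.
#' @param annotation optional frame-annotation tibble (see
#'   [annotate_frame()]) overlaid as points colored by visibility.
#' @param ... ignored.
#' @return A ggplot object.
#' @method autoplot stick_frame
#' @export
autoplot.stick_frame <- function(object, annotation = NULL, ...) {
  df <- tibble::as_tibble(expand.grid(row = seq_len(nrow(object)),
                                      col = seq_len(ncol(object))))
  df$value <- as.vector(unclass(object))  # column-major, row varies fastest
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col - 0.5,
                                        y = .data$row - 0.5)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "y (px)")
  if (!is.null(annotation)) {
    p <- p + ggplot2::geom_point(
      data = annotation,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$visible),
      inherit.aes = FALSE, size = 1.2) +
      ggplot2::scale_color_manual(values = c(`TRUE` = "#2ecc71",
                                             `FALSE` = "#e74c3c"))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
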