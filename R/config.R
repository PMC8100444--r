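#' Serialize the scene configuration to YAML
#'
#' Writes the body geometry, camera and appearance blocks (the documented
#' schema consumed by the command-line tool) so a rendering run is fully
#' reproducible from its config plus a seed.
#'
#' @param path output YAML file.
#' @param geometry a [body_geometry()].
#' @param camera a [make_camera()].
#' @param appearance a [default_appearance()].
#' @return `path`, invisibly.
#' @export
write_stickgen_config <- function(path, geometry = default_geometry(),
                                  camera = make_camera(),
                                  appearance = default_appearance()) {
  cfg <- list(
    geometry = list(
      trunk = as.list(geometry$trunk),
      legs = lapply(as.list(as.data.frame(geometry$legs)), as.numeric),
      attachments = list(
        pair = as.numeric(geometry$attachments$pair),
        segment = geometry$attachments$segment,
        along = as.numeric(geometry$attachments$along),
        lateral = as.numeric(geometry$attachments$lateral)),
      height = geometry$height,
      trunk_radii = as.list(geometry$trunk_radii),
      leg_radii = as.list(geometry$leg_radii),
      sphere_radii = as.list(geometry$sphere_radii),
      trunk_landmarks = as.list(geometry$trunk_landmarks),
      scale = geometry$scale),
    camera = list(width = camera$width, height_px = camera$height_px,
                  fov_deg = camera$fov_deg, fov_axis = camera$fov_axis,
                  height = camera$height, roll = camera$roll,
                  offset = as.numeric(camera$offset)),
    appearance = unclass(appearance))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a scene configuration written by [write_stickgen_config()]
#'
#' @param path YAML file.
#' @return List with reconstructed `geometry`, `camera` and `appearance`
#'   objects.
#' @export
read_stickgen_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$geometry
  geometry <- body_geometry(
    trunk = unlist(g$trunk),
    legs = tibble::as_tibble(g$legs),
    attachments = tibble::as_tibble(g$attachments),
    height = g$height,
    trunk_radii = unlist(g$trunk_radii),
    leg_radii = unlist(g$leg_radii),
    sphere_radii = unlist(g$sphere_radii),
    trunk_landmarks = unlist(g$trunk_landmarks),
    scale = g$scale)
  cm <- cfg$camera
  camera <- make_camera(width = cm$width, height_px = cm$height_px,
                        fov_deg = cm$fov_deg, height = cm$height,
                        roll = cm$roll, offset = cm$offset,
                        fov_axis = cm$fov_axis)
  ap <- cfg$appearance
  appearance <- default_appearance(ap$background, ap$body_gray, ap$ambient)
  list(geometry = geometry, camera = camera, appearance = appearance)
}
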