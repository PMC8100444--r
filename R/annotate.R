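#' Automatic ground-truth annotation of one frame
#'
#' Projects all 22 landmarks through the camera and attaches visibility
#' flags. Landmarks that are occluded or fall outside the image keep their
#' projected coordinates but are flagged `visible = FALSE`.
#'
#' @param posture a `posture3d`.
#' @param camera a [make_camera()].
#' @param visibility optional precomputed [compute_visibility()] tibble.
#' @return Tibble with `landmark` (in [landmark_names()] order), `x`, `y`
#'   (px) and `visible`.
#' @export
annotate_frame <- function(posture, camera = make_camera(), visibility = NULL) {
  stopifnot(inherits(posture, "posture3d"))
  if (is.null(visibility)) visibility <- compute_visibility(posture, camera)
  proj <- project_points(camera, posture$landmarks)
  tibble::tibble(landmark = posture$landmarks$landmark,
                 x = proj$x, y = proj$y,
                 visible = visibility$visible & proj$valid)
}

#' Generate a fully annotated synthetic video set
#'
#' Runs the whole per-frame pipeline of a [video_spec()]: draw the frame's
#' transformation, build the posture from the trajectory's joint angles,
#' apply the transformation, compute visibility, annotate, and (optionally)
#' render and write the frame. Also draws the spec's training-frame
#' selection. Everything is driven by the spec's seed, so a rerun
#' reproduces the annotation files bit for bit.
#'
#' @param spec a [video_spec()].
#' @param trajectory joint-angle trajectory ([generate_gait()] or
#'   [read_joint_angles()]); must cover `start_frame + n_frames - 1` rows.
#' @param geometry a [body_geometry()].
#' @param camera a [make_camera()].
#' @param out_dir optional run directory; when given, frames (if
#'   `render = TRUE`), annotations in both dialects, the per-frame
#'   transform log and a YAML manifest are written there.
#' @param render render and write PNG frames (requires `out_dir`).
#' @param appearance a [default_appearance()].
#' @return An object of class `annotated_dataset`: list with
#'   `annotations` (tibble `frame`, `landmark`, `x`, `y`, `visible`),
#'   `transforms` (per-frame tibble), `train_frames`, `spec`,
#'   `frame_paths`.
#' @export
generate_video_set <- function(spec, trajectory,
                               geometry = default_geometry(),
                               camera = make_camera(),
                               out_dir = NULL, render = !is.null(out_dir),
                               appearance = default_appearance()) {
  stopifnot(inherits(spec, "video_spec"))
  need <- spec$start_frame + spec$n_frames - 1L
  if (nrow(trajectory) < need)
    rlang::abort(paste0("trajectory has ", nrow(trajectory),
                        " frames but the spec needs ", need))
  if (render && is.null(out_dir))
    rlang::abort("rendering requires an output directory")

  drawn <- with_local_seed(spec$seed, {
    list(transforms = sample_transforms(spec$n_frames, spec$ranges),
         train = sort(sample.int(spec$n_frames, spec$n_train)))
  })
  transforms <- drawn$transforms
  transforms$frame <- seq_len(spec$n_frames)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (render)
      dir.create(file.path(out_dir, "frames"), showWarnings = FALSE)
  }

  ann <- vector("list", spec$n_frames)
  paths <- if (render) character(spec$n_frames) else NULL
  for (i in seq_len(spec$n_frames)) {
    angles <- trajectory[spec$start_frame + i - 1L, ]
    posture <- build_posture(angles, geometry)
    tr <- apply_transform(posture, camera, transforms[i, ])
    a <- annotate_frame(tr$posture, tr$camera)
    a$frame <- i
    ann[[i]] <- a
    if (render) {
      img <- render_frame(tr$posture, tr$camera, appearance)
      paths[i] <- file.path("frames", sprintf("frame_%05d.png", i))
      write_frame_png(img, file.path(out_dir, paths[i]))
    }
  }
  annotations <- dplyr::bind_rows(ann)[, c("frame", "landmark", "x", "y",
                                           "visible")]
  ds <- structure(list(annotations = annotations, transforms = transforms,
                       train_frames = drawn$train, spec = spec,
                       frame_paths = paths),
                  class = "annotated_dataset")
  if (!is.null(out_dir)) {
    export_annotations(ds, file.path(out_dir, "annotations.csv"),
                       dialect = "internal")
    readr::write_csv(transforms, file.path(out_dir, "transforms.csv"))
    manifest <- list(
      name = spec$name, n_frames = spec$n_frames, n_train = spec$n_train,
      seed = spec$seed, start_frame = spec$start_frame,
      train_frames = drawn$train,
      ranges = unclass(spec$ranges),
      camera = unclass(camera)[c("width", "height_px", "fov_deg", "fov_axis",
                                 "height", "roll", "offset")],
      geometry_scale = geometry$scale,
      rendered = render)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  ds
}

#' @export
print.annotated_dataset <- function(x, ...) {
  cat("<annotated_dataset> ", x$spec$name, ": ", x$spec$n_frames,
      " frames x ", length(unique(x$annotations$landmark)), " landmarks, ",
      length(x$train_frames), " training frames\n", sep = "")
  invisible(x)
}

#' Export annotations
#'
#' Two dialects: `"internal"` is a flat CSV (`frame`, `landmark`, `x`,
#' `y`, `visible`) that preserves everything; `"dlc"` is the
#' DeepLabCut-compatible labeled-data layout with a three-row header
#' (scorer / bodyparts / coords), one row per frame and an x/y column pair
#' per body part, where invisible landmarks become empty cells.
#'
#' @param dataset an `annotated_dataset` (or a bare annotation tibble).
#' @param path output CSV file.
#' @param dialect `"internal"` or `"dlc"`.
#' @param scorer scorer name written into the DLC header.
#' @param blank_invisible blank out invisible landmarks in the DLC dialect
#'   (default TRUE; set FALSE to keep their coordinates).
#' @return `path`, invisibly.
#' @export
export_annotations <- function(dataset, path,
                               dialect = c("internal", "dlc"),
                               scorer = "stickgen",
                               blank_invisible = TRUE) {
  dialect <- match.arg(dialect)
  ann <- if (inherits(dataset, "annotated_dataset")) dataset$annotations
         else tibble::as_tibble(dataset)
  if (!nrow(ann)) rlang::abort("cannot export an empty dataset")
  if (dialect == "internal") {
    readr::write_csv(ann, path)
    return(invisible(path))
  }
  parts <- unique(ann$landmark)
  wide <- tidyr::pivot_wider(ann, id_cols = "frame",
                             names_from = "landmark",
                             values_from = c("x", "y", "visible"),
                             names_glue = "{landmark}.{.value}")
  hdr1 <- c("scorer", rep(scorer, 2 * length(parts)))
  hdr2 <- c("bodyparts", rep(parts, each = 2))
  hdr3 <- c("coords", rep(c("x", "y"), length(parts)))
  rows <- lapply(seq_len(nrow(wide)), function(i) {
    vals <- unlist(lapply(parts, function(p) {
      xy <- c(wide[[paste0(p, ".x")]][i], wide[[paste0(p, ".y")]][i])
      if (blank_invisible && !isTRUE(wide[[paste0(p, ".visible")]][i]))
        c("", "")
      else format(xy, digits = 17, trim = TRUE, scientific = FALSE)
    }))
    paste(c(sprintf("frame_%05d.png", wide$frame[i]), vals), collapse = ",")
  })
  writeLines(c(paste(hdr1, collapse = ","), paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ","), unlist(rows)), path)
  invisible(path)
}

#' Read annotations written by [export_annotations()]
#'
#' @param path CSV file.
#' @param dialect `"internal"` or `"dlc"`. In the DLC dialect empty cells
#'   come back as `NA` coordinates with `visible = FALSE`.
#' @return Annotation tibble (`frame`, `landmark`, `x`, `y`, `visible`).
#' @export
read_annotations <- function(path, dialect = c("internal", "dlc")) {
  dialect <- match.arg(dialect)
  if (dialect == "internal") {
    ann <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             frame = readr::col_integer(),
                             landmark = readr::col_character(),
                             x = readr::col_double(),
                             y = readr::col_double(),
                             visible = readr::col_logical()))
    return(ann)
  }
  lines <- readLines(path)
  if (length(lines) < 4L || !startsWith(lines[1], "scorer"))
    rlang::abort("not a DLC-dialect annotation file")
  parts <- strsplit(lines[2], ",")[[1]][-1][c(TRUE, FALSE)]
  body <- lines[-(1:3)]
  rows <- purrr::map_dfr(seq_along(body), function(i) {
    cells <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    cells <- c(cells, rep("", 1 + 2 * length(parts) - length(cells)))
    frame <- as.integer(gsub("\\D", "", basename(cells[1])))
    x <- suppressWarnings(as.numeric(cells[seq(2, by = 2,
                                               length.out = length(parts))]))
    y <- suppressWarnings(as.numeric(cells[seq(3, by = 2,
                                               length.out = length(parts))]))
    tibble::tibble(frame = frame, landmark = parts, x = x, y = y,
                   visible = !is.na(x) & !is.na(y))
  })
  rows
}

#' Split frames into training and test sets by fraction
#'
#' Draws `floor(fraction * n_frames)` training frames uniformly without
#' replacement; the remainder are test frames. The split is a disjoint,
#' exhaustive partition and deterministic per seed.
#'
#' @param n_frames total number of frames.
#' @param fraction training fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @return List with sorted integer vectors `train` and `test`.
#' @export
split_training_fraction <- function(n_frames, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    rlang::abort("training fraction must lie strictly between 0 and 1")
  n_train <- floor(fraction * n_frames)
  train <- with_local_seed(seed, sort(sample.int(n_frames, n_train)))
  list(train = train, test = setdiff(seq_len(n_frames), train))
}
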