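#' Declarative specification of one synthetic video
#'
#' @param name short identifier (e.g. `"TRS"`).
#' @param n_frames number of frames to render (>= 1).
#' @param ranges a [transform_ranges()] drawn from independently per frame.
#' @param n_train number of training frames sampled from the video
#'   (<= `n_frames`).
#' @param seed integer seed driving the per-frame transform draws and the
#'   training-frame selection.
#' @param start_frame first trajectory frame to use.
#' @return A list of class `video_spec`.
#' @export
video_spec <- function(name, n_frames, ranges = transform_ranges(),
                       n_train = n_frames, seed = 1L, start_frame = 1L) {
  if (n_frames < 1) rlang::abort("a video needs at least one frame")
  if (n_train > n_frames)
    rlang::abort("training sample cannot exceed the frame count")
  structure(list(name = name, n_frames = as.integer(n_frames),
                 ranges = ranges, n_train = as.integer(n_train),
                 seed = as.integer(seed), start_frame = as.integer(start_frame)),
            class = "video_spec")
}

#' @export
print.video_spec <- function(x, ...) {
  on <- c("T", "R", "S")[c(x$ranges$translate, x$ranges$rotate, x$ranges$scale)]
  cat("<video_spec> ", x$name, ": ", x$n_frames, " frames, ",
      x$n_train, " training frames, transforms {",
      paste(on, collapse = ""), "}, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Transformation-subset videos (Experiment I design)
#'
#' One video per nonempty subset of \{translation, rotation, scaling\}:
#' T, R, S, TR, TS, RS and TRS, each 1,600 frames long with per-frame
#' random transforms and a 200-frame training selection. The TRS video
#' doubles as the benchmark test video.
#'
#' @param n_frames frames per video.
#' @param n_train training frames sampled per video.
#' @param base_seed seed for the first video; subsequent videos use
#'   consecutive seeds.
#' @return Named list of 7 [video_spec()]s.
#' @export
build_experiment1_designs <- function(n_frames = 1600, n_train = 200,
                                      base_seed = 101L) {
  subsets <- list(T = c(TRUE, FALSE, FALSE), R = c(FALSE, TRUE, FALSE),
                  S = c(FALSE, FALSE, TRUE), TR = c(TRUE, TRUE, FALSE),
                  TS = c(TRUE, FALSE, TRUE), RS = c(FALSE, TRUE, TRUE),
                  TRS = c(TRUE, TRUE, TRUE))
  out <- purrr::imap(subsets, function(flags, nm) {
    video_spec(nm, n_frames,
               transform_ranges(translate = flags[1], rotate = flags[2],
                                scale = flags[3]),
               n_train = n_train,
               seed = base_seed + match(nm, names(subsets)) - 1L)
  })
  out
}

#' Cumulative discrete-rotation videos (Experiment II design)
#'
#' Eight base videos of 800 frames each, every frame of video *i* rotated
#' by the fixed angle `(i - 1) * 45` degrees (no translation or scaling).
#' Training set *k* draws 200 frames uniformly from the union of base
#' videos 1..k, so set 1 contains a single orientation and set 8 all
#' eight. The benchmark test video is Experiment I's TRS video.
#'
#' @param n_frames frames per base video.
#' @param n_train training frames per training set.
#' @param base_seed seed for the first base video.
#' @return List with `videos` (8 [video_spec()]s) and `training_sets`
#'   (tibble: `k`, `rotations_deg` list-column, `n_train`, `seed`).
#' @export
build_experiment2_designs <- function(n_frames = 800, n_train = 200,
                                      base_seed = 201L) {
  angles_deg <- seq(0, 315, by = 45)
  videos <- purrr::map(seq_along(angles_deg), function(i) {
    video_spec(paste0("rot", angles_deg[i]), n_frames,
               transform_ranges(rotate = angles_deg[i] != 0,
                                rotation_support = angles_deg[i] * pi / 180),
               n_train = n_frames, seed = base_seed + i - 1L)
  })
  names(videos) <- paste0("rot", angles_deg)
  training_sets <- tibble::tibble(
    k = 1:8,
    rotations_deg = purrr::map(1:8, ~angles_deg[seq_len(.x)]),
    n_train = as.integer(n_train),
    seed = base_seed + 100L + 1:8,
    sampling = "uniform over the union of base videos 1..k")
  list(videos = videos, training_sets = training_sets)
}

#' Synthetic pre-training video (Experiment III design)
#'
#' A video whose per-frame transform is drawn from the 8 x 5 grid of
#' discrete rotations (0-315 degrees in 45-degree increments) crossed with
#' the five scale factors \{0.5, 0.7, 1.0, 1.3, 1.5\}; 8,000 frames are
#' selected for pre-training.
#'
#' @param n_frames video length; the full video is used for the
#'   8,000-frame pre-training selection.
#' @param base_seed seed.
#' @return A [video_spec()] whose ranges support is the 40-combination grid.
#' @export
build_pretraining_design <- function(n_frames = 8000, base_seed = 301L) {
  video_spec("pretrain", n_frames,
             transform_ranges(rotate = TRUE, scale = TRUE,
                              rotation_support = seq(0, 315, 45) * pi / 180,
                              scale_support = c(0.5, 0.7, 1.0, 1.3, 1.5)),
             n_train = 8000L, seed = base_seed)
}

#' Transform support of a pretraining-style spec
#'
#' @param spec a [video_spec()] with discrete rotation and scale supports.
#' @return Tibble of all (rotation, scale) combinations in the support.
#' @export
transform_support_grid <- function(spec) {
  stopifnot(inherits(spec, "video_spec"))
  rot <- if (identical(spec$ranges$rotation_support, "uniform"))
    rlang::abort("continuous rotation support has no finite grid")
  else spec$ranges$rotation_support
  tidyr::expand_grid(rotation = rot, scale = spec$ranges$scale_support)
}

#' Model-type by training-fraction grid (Experiment III design)
#'
#' Two model types (trained on experimental frames only, or pre-trained on
#' synthetic frames first) crossed with four training fractions of the 286
#' experimental frames and five replicate models each: 40 runs.
#'
#' @param fractions training fractions of the experimental frame set.
#' @param n_replicates replicate models per cell.
#' @param n_frames number of annotated experimental frames.
#' @param base_seed first replicate seed.
#' @return Tibble with one row per run: `model_type`, `fraction`,
#'   `replicate`, `n_train`, `seed`.
#' @export
build_experiment3_grid <- function(fractions = c(0.1, 0.2, 0.5, 0.8),
                                   n_replicates = 5, n_frames = 286,
                                   base_seed = 401L) {
  g <- tidyr::expand_grid(
    model_type = c("experimental_only", "synthetic_experimental"),
    fraction = fractions,
    replicate = seq_len(n_replicates))
  g$n_train <- floor(g$fraction * n_frames)
  g$seed <- base_seed + seq_len(nrow(g)) - 1L
  g
}
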