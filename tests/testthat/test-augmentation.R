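test_that("disabled components draw identity transforms", {
  tr <- sample_transform(transform_ranges())
  expect_equal(unlist(tr), c(tx = 0, ty = 0, rotation = 0, scale = 1))
})

test_that("enabled components respect their supports and are uniform", {
  set.seed(99)
  r <- transform_ranges(translate = TRUE, rotate = TRUE, scale = TRUE)
  d <- sample_transforms(1e4, r)
  # translation never leaves the [-30, 30] square
  expect_true(all(abs(d$tx) <= 30 & abs(d$ty) <= 30))
  # rotation stays in [0, 2*pi)
  expect_true(all(d$rotation >= 0 & d$rotation < 2 * pi))
  # discrete scale set is drawn uniformly: each frequency 0.2 +/- 0.02
  freq <- table(d$scale) / nrow(d)
  expect_equal(sort(unique(d$scale)), c(0.5, 0.7, 1.0, 1.3, 1.5))
  expect_true(all(abs(freq - 0.2) < 0.02))
  expect_error(transform_ranges(scale = TRUE, scale_support = numeric()),
               "empty")
})

test_that("apply_transform realizes exact pixel-space semantics", {
  cam <- make_camera()
  set.seed(3)
  pts <- cbind(runif(12, -35, 35), runif(12, -35, 35))
  pos <- planar_posture(pts)
  base <- annotate_frame(pos, cam)

  # identity spec changes nothing
  id <- apply_transform(pos, cam, tibble::tibble(tx = 0, ty = 0,
                                                 rotation = 0, scale = 1))
  expect_equal(annotate_frame(id$posture, id$camera)[, c("x", "y")],
               base[, c("x", "y")], tolerance = 1e-12)

  # pure translation: every projection shifts by exactly the request
  tr <- apply_transform(pos, cam, tibble::tibble(tx = 30, ty = 0,
                                                 rotation = 0, scale = 1))
  moved <- annotate_frame(tr$posture, tr$camera)
  expect_equal(moved$x, base$x + 30, tolerance = 1e-6)
  expect_equal(moved$y, base$y, tolerance = 1e-6)

  # half-turn rotation: point reflection through the image centre
  rot <- apply_transform(pos, cam, tibble::tibble(tx = 0, ty = 0,
                                                  rotation = pi, scale = 1))
  flipped <- annotate_frame(rot$posture, rot$camera)
  expect_equal(flipped$x, 640 - base$x, tolerance = 1e-6)
  expect_equal(flipped$y, 480 - base$y, tolerance = 1e-6)

  # planar scaling scales centre-relative projections
  sc <- apply_transform(pos, cam, tibble::tibble(tx = 0, ty = 0,
                                                 rotation = 0, scale = 1.5))
  scaled <- annotate_frame(sc$posture, sc$camera)
  expect_equal(scaled$x - 320, 1.5 * (base$x - 320), tolerance = 1e-6)
  expect_equal(scaled$y - 240, 1.5 * (base$y - 240), tolerance = 1e-6)
})

test_that("annotation commutes with arbitrary transforms on planar scenes", {
  cam <- make_camera()
  set.seed(8)
  pts <- cbind(runif(10, -25, 25), runif(10, -25, 25))
  pos <- planar_posture(pts)
  base <- annotate_frame(pos, cam)
  specs <- sample_transforms(6, transform_ranges(translate = TRUE,
                                                 rotate = TRUE, scale = TRUE))
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    out <- apply_transform(pos, cam, s)
    got <- annotate_frame(out$posture, out$camera)
    # pixel-space prediction: scale about centre, rotate by -theta, shift
    dx <- s$scale * (base$x - 320); dy <- s$scale * (base$y - 240)
    ex <- 320 + cos(-s$rotation) * dx - sin(-s$rotation) * dy + s$tx
    ey <- 240 + sin(-s$rotation) * dx + cos(-s$rotation) * dy + s$ty
    expect_equal(got$x, ex, tolerance = 1e-6)
    expect_equal(got$y, ey, tolerance = 1e-6)
  }
})

test_that("the transformation-subset design enumerates all 7 videos", {
  d <- build_experiment1_designs()
  expect_length(d, 7)
  expect_setequal(names(d), c("T", "R", "S", "TR", "TS", "RS", "TRS"))
  flags <- t(sapply(d, function(s) c(s$ranges$translate, s$ranges$rotate,
                                     s$ranges$scale)))
  expect_equal(nrow(unique(flags)), 7)      # bijection with nonempty subsets
  expect_true(all(rowSums(flags) >= 1))
  for (s in d) {
    expect_equal(s$n_frames, 1600L)
    expect_equal(s$n_train, 200L)
  }
})

test_that("the cumulative-rotation design covers 45-degree steps", {
  d <- build_experiment2_designs()
  expect_length(d$videos, 8)
  for (i in seq_along(d$videos))
    expect_equal(d$videos[[i]]$n_frames, 800L)
  expect_equal(d$training_sets$k, 1:8)
  expect_equal(d$training_sets$rotations_deg[[3]], c(0, 45, 90))
  expect_equal(d$training_sets$rotations_deg[[1]], 0)
  expect_equal(d$training_sets$rotations_deg[[8]], seq(0, 315, 45))
  expect_true(all(d$training_sets$n_train == 200L))
})

test_that("the pre-training design spans the 8 x 5 rotation-scale grid", {
  d <- build_pretraining_design()
  grid <- transform_support_grid(d)
  expect_equal(nrow(grid), 40)
  expect_equal(nrow(dplyr::distinct(grid)), 40)
  expect_equal(d$n_train, 8000L)
  set.seed(1)
  draws <- sample_transforms(500, d$ranges)
  expect_true(all(draws$rotation %in% (seq(0, 315, 45) * pi / 180)))
  expect_true(all(draws$scale %in% c(0.5, 0.7, 1.0, 1.3, 1.5)))
})

test_that("video generation is reproducible for a fixed seed", {
  spec <- video_spec("TRS-mini", 6,
                     transform_ranges(translate = TRUE, rotate = TRUE,
                                      scale = TRUE),
                     n_train = 3, seed = 12)
  traj <- generate_gait(6)
  a <- generate_video_set(spec, traj)
  b <- generate_video_set(spec, traj)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$transforms, b$transforms)
  expect_identical(a$train_frames, b$train_frames)
  expect_error(generate_video_set(spec, generate_gait(3)), "3 frames")
})
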