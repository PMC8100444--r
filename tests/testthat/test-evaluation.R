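test_that("score-map argmax returns bin centres with row-major tie-breaks", {
  m <- matrix(0, 60, 80)
  m[10, 25] <- 0.9
  got <- scoremap_argmax(m, stride = 8)
  expect_equal(c(got$x, got$y), c((25 - 1 + 0.5) * 8, (10 - 1 + 0.5) * 8))
  expect_equal(got$confidence, 0.9)
  expect_false(got$tie)

  # two equal maxima: earlier row-major bin wins, tie flagged
  m2 <- matrix(0, 4, 4); m2[2, 3] <- 0.5; m2[3, 1] <- 0.5
  t2 <- scoremap_argmax(m2)
  # brute-force scan oracle
  best <- NULL
  for (r in 1:4) for (c in 1:4)
    if (is.null(best) && m2[r, c] == max(m2)) best <- c(r, c)
  expect_equal(c(t2$y, t2$x), (best - 1 + 0.5) * 8)
  expect_true(t2$tie)

  # uniform map: first bin, flagged
  u <- scoremap_argmax(matrix(1, 3, 3))
  expect_equal(c(u$x, u$y), c(4, 4))
  expect_true(u$tie)

  # all-zero map: confidence 0 and degenerate flag
  z <- scoremap_argmax(matrix(0, 3, 3))
  expect_equal(z$confidence, 0)
  expect_true(z$degenerate)
})

test_that("the error metric and the exclusion rule follow the contract", {
  truth <- synthetic_truth(5)
  # perfect predictions: zero errors, nothing excluded
  perfect <- dplyr::mutate(truth[, c("frame", "landmark", "x", "y")],
                           confidence = 1)
  rep0 <- evaluate_predictions(perfect, truth)
  expect_true(all(rep0$errors$error == 0))
  expect_equal(rep0$n_excluded, 0)

  # a fixed (3, 4) offset yields error 5 everywhere (Pythagorean oracle)
  off <- dplyr::mutate(perfect, x = x + 3, y = y + 4)
  rep1 <- evaluate_predictions(off, truth)
  expect_true(all(abs(rep1$errors$error - 5) < 1e-12))

  # sub-cutoff confidence excludes exactly those entries, bookkeeping intact
  off$confidence[c(2, 10)] <- 0.05
  rep2 <- evaluate_predictions(off, truth, cutoff = 0.10)
  expect_equal(rep2$n_excluded, 2)
  expect_equal(rep2$n_total, nrow(truth))
  expect_equal(sum(!rep2$errors$excluded) + rep2$n_excluded, rep2$n_total)
  g <- glance(rep2)
  expect_equal(g$n_included + g$n_excluded, g$n_total)

  # metric axioms: symmetry in prediction/truth, zero iff equal
  a_tab <- off[, c("frame", "landmark", "x", "y")]
  b_tab <- truth[, c("frame", "landmark", "x", "y")]
  r_ab <- evaluate_predictions(dplyr::mutate(a_tab, confidence = 1), b_tab)
  r_ba <- evaluate_predictions(dplyr::mutate(b_tab, confidence = 1), a_tab)
  expect_equal(sort(r_ab$errors$error), sort(r_ba$errors$error))
  expect_true(all(r_ab$errors$error > 0))

  # unknown labels are named in the rejection
  bad <- dplyr::mutate(perfect, landmark = replace(landmark, 1, "antenna"))
  expect_error(evaluate_predictions(bad, truth), "antenna")
})

test_that("per-feature summaries sort by spread with group tags", {
  set.seed(5)
  truth <- synthetic_truth(40)
  pred <- dplyr::mutate(truth[, c("frame", "landmark", "x", "y")],
                        confidence = 1)
  # thorax/head features: tight errors; tarsi: wide errors
  noisy <- grepl("TiTa", pred$landmark)
  pred$x <- pred$x + rnorm(nrow(pred), sd = ifelse(noisy, 10, 1))
  rep <- evaluate_predictions(pred, truth)
  per <- summarize_by_feature(rep)
  expect_equal(nrow(per), 22)
  expect_true(all(diff(per$sd) >= 0))
  expect_true(all(per$group[per$landmark %in%
                              c("Head", "ProMeso", "MesoMeta", "MetaAbd")] ==
                    "head/thorax"))
  first_group <- per$group[1:6]
  expect_false(any(first_group == "tibia-tarsus"))
  tail_group <- per$group[17:22]
  expect_true(all(tail_group == "tibia-tarsus"))
  expect_equal(sum(per$n), sum(!rep$errors$excluded))

  # degenerate all-zero errors: every SD is 0
  rep0 <- evaluate_predictions(
    dplyr::mutate(truth[, c("frame", "landmark", "x", "y")], confidence = 1),
    truth)
  expect_true(all(summarize_by_feature(rep0)$sd == 0))
})

test_that("the mock predictor recovers its design parameters", {
  truth <- synthetic_truth(455)           # 455 x 22 = 10,010 entries
  n <- nrow(truth)

  # noiseless mock equals the truth
  p0 <- mock_predictor(truth, noise_sd = 0, seed = 2)
  expect_equal(p0$x, truth$x)
  expect_equal(p0$y, truth$y)

  # Rayleigh mean: E|err| = sigma * sqrt(pi/2), within 3 SE
  sigma <- 2
  p1 <- mock_predictor(truth, noise_sd = sigma, seed = 3)
  r1 <- evaluate_predictions(p1, truth)
  se <- sigma * sqrt(2 - pi / 2) / sqrt(n)
  expect_lt(abs(mean(r1$errors$error) - sigma * sqrt(pi / 2)), 3 * se)

  # low-confidence rate drives the exclusion count (binomial oracle)
  p2 <- mock_predictor(truth, noise_sd = 1, lowconf_rate = 0.1, seed = 4)
  r2 <- evaluate_predictions(p2, truth)
  expect_lt(abs(r2$n_excluded / n - 0.1), 3 * sqrt(0.1 * 0.9 / n))

  # mislocated entries land far away
  p3 <- mock_predictor(truth, noise_sd = 0.5, miss_rate = 0.2, seed = 5)
  r3 <- evaluate_predictions(p3, truth)
  expect_gt(mean(r3$errors$error > 10), 0.1)

  expect_error(mock_predictor(truth, miss_rate = 2), "rates")
  # identical seeds give identical predictions
  expect_identical(mock_predictor(truth, 2, 0.1, 0.1, seed = 9),
                   mock_predictor(truth, 2, 0.1, 0.1, seed = 9))
})

test_that("the harness executes design grids and tolerates failures", {
  grid <- build_experiment3_grid()
  expect_equal(nrow(grid), 40)
  expect_equal(dplyr::n_distinct(grid$model_type), 2)
  expect_equal(dplyr::n_distinct(grid$fraction), 4)
  expect_equal(sort(unique(grid$n_train)), floor(c(0.1, 0.2, 0.5, 0.8) * 286))

  truth <- synthetic_truth(30)
  # mock network whose noise shrinks with training fraction
  predictor <- function(truth, design) {
    mock_predictor(truth, noise_sd = 6 * (1 - design$fraction),
                   seed = design$seed)
  }
  res <- run_experiment_harness(grid, predictor, truth)
  expect_equal(nrow(res$results), 40)
  expect_equal(nrow(res$failures), 0)
  med <- res$results |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(m = median(.data$median_error), .groups = "drop") |>
    dplyr::arrange(.data$fraction)
  expect_true(all(diff(med$m) < 0))        # monotone improvement

  # determinism under identical seeds
  res2 <- run_experiment_harness(grid, predictor, truth)
  expect_equal(res$results, res2$results)

  # a failing run is recorded and the grid continues
  flaky <- function(truth, design) {
    if (design$replicate == 3) stop("GPU on fire")
    mock_predictor(truth, noise_sd = 1, seed = design$seed)
  }
  resf <- run_experiment_harness(grid[1:10, ], flaky, truth)
  expect_equal(nrow(resf$failures), 2)
  expect_match(resf$failures$message[1], "GPU")
  expect_equal(sum(!sapply(resf$reports, is.null)), 8)

  # feature-by-model matrix feeds the Friedman interface (22 x k)
  mat <- harness_feature_matrix(res)
  expect_equal(dim(mat), c(22, 40))
  ft <- friedman_rank_test(mat[, 1:7])
  expect_true(ft$p_value >= 0 && ft$p_value <= 1)
})
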