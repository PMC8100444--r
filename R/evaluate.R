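#' Argmax position estimate of a score map
#'
#' Networks emit per-landmark confidence grids at a fixed stride (8 px
#' bins by default); the brightest bin is the position estimate. The
#' returned pixel position is the centre of the winning bin. Ties are
#' broken by row-major scan order (first row, then column) and flagged.
#'
#' @param map numeric matrix of non-negative confidences (rows = image
#'   rows / stride, columns = image columns / stride).
#' @param stride pixels per bin.
#' @return One-row tibble: `x`, `y` (px), `confidence`, `tie`,
#'   `degenerate` (TRUE when the map is all zero).
#' @export
scoremap_argmax <- function(map, stride = 8) {
  if (!is.matrix(map) || !length(map)) rlang::abort("score map must be a nonempty matrix")
  if (any(map < 0)) rlang::abort("score map values must be non-negative")
  mx <- max(map)
  hits <- which(map == mx, arr.ind = TRUE)
  ord <- order(hits[, "row"], hits[, "col"])
  r <- unname(hits[ord[1], "row"])
  c <- unname(hits[ord[1], "col"])
  tibble::tibble(x = (c - 1 + 0.5) * stride, y = (r - 1 + 0.5) * stride,
                 confidence = mx, tie = nrow(hits) > 1L,
                 degenerate = mx == 0)
}

# Coerce an annotated_dataset or tibble to the bare annotation table.
truth_table <- function(truth) {
  if (inherits(truth, "annotated_dataset")) truth$annotations
  else tibble::as_tibble(truth)
}

#' Score predictions against ground truth
#'
#' Computes the per-(frame, landmark) Euclidean pixel error between a
#' prediction set and the automatic ground truth. Entries whose
#' confidence falls below the cut-off (default 10%) are excluded from all
#' summary statistics but kept in the report with an exclusion marker —
#' these are typically occluded or out-of-frame body features.
#'
#' @param pred tibble with `frame`, `landmark`, `x`, `y`, `confidence`
#'   (confidence in `[0, 1]`).
#' @param truth an `annotated_dataset` or its annotation tibble.
#' @param cutoff confidence threshold below which entries are excluded.
#' @return An object of class `error_report`; see [tidy.error_report()]
#'   and [glance.error_report()].
#' @export
evaluate_predictions <- function(pred, truth, cutoff = 0.10) {
  pred <- tibble::as_tibble(pred)
  tt <- truth_table(truth)
  need <- c("frame", "landmark", "x", "y", "confidence")
  if (!all(need %in% names(pred)))
    rlang::abort(paste0("prediction set must have columns: ",
                        paste(need, collapse = ", ")))
  if (any(pred$confidence < 0 | pred$confidence > 1, na.rm = TRUE))
    rlang::abort("confidences must lie in [0, 1]")
  bad <- setdiff(unique(pred$landmark), unique(tt$landmark))
  if (length(bad))
    rlang::abort(paste0("prediction label(s) not in ground truth: ",
                        paste(bad, collapse = ", ")))
  joined <- dplyr::inner_join(pred, tt, by = c("frame", "landmark"),
                              suffix = c("_pred", "_true"))
  if (nrow(joined) < nrow(pred))
    rlang::abort("some predictions have no matching ground-truth entry")
  errors <- dplyr::transmute(
    joined, frame = .data$frame, landmark = .data$landmark,
    error = sqrt((.data$x_pred - .data$x_true)^2 +
                   (.data$y_pred - .data$y_true)^2),
    confidence = .data$confidence,
    excluded = .data$confidence < cutoff)
  structure(list(errors = errors, cutoff = cutoff,
                 n_total = nrow(errors),
                 n_excluded = sum(errors$excluded)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  inc <- x$errors$error[!x$errors$excluded]
  cat("<error_report> ", x$n_total, " entries, ", x$n_excluded,
      " excluded below confidence ", x$cutoff, "\n", sep = "")
  if (length(inc))
    cat("  pixel error: mean ", round(mean(inc), 3), ", median ",
        round(median(inc), 3), ", IQR ", round(IQR(inc), 3), "\n", sep = "")
  invisible(x)
}

#' Per-landmark error distributions
#'
#' @param x an `error_report`.
#' @param groups named character vector mapping a landmark-label pattern
#'   to a proximal-to-distal group tag (defaults follow the head/thorax,
#'   coxa, femur-tibia, tibia-tarsus gradient).
#' @param ... ignored.
#' @return Tibble with one row per landmark: `n` included entries,
#'   `n_excluded`, `mean`, `median`, `iqr`, `sd` of the pixel error and
#'   the `group` tag, sorted by increasing standard deviation.
#' @method tidy error_report
#' @export
tidy.error_report <- function(x, groups = c("CxTr" = "coxa",
                                            "FeTi" = "femur-tibia",
                                            "TiTa" = "tibia-tarsus"), ...) {
  tag <- function(lbl) {
    hit <- purrr::detect_index(names(groups), ~grepl(.x, lbl, fixed = TRUE))
    if (hit > 0) unname(groups[hit]) else "head/thorax"
  }
  out <- x$errors |>
    dplyr::group_by(.data$landmark) |>
    dplyr::summarise(
      n = sum(!.data$excluded),
      n_excluded = sum(.data$excluded),
      mean = mean(.data$error[!.data$excluded]),
      median = median(.data$error[!.data$excluded]),
      iqr = IQR(.data$error[!.data$excluded]),
      sd = if (sum(!.data$excluded) > 1) sd(.data$error[!.data$excluded]) else 0,
      .groups = "drop")
  out$group <- vapply(out$landmark, tag, character(1))
  out[order(out$sd), ]
}

#' @rdname tidy.error_report
#' @export
summarize_by_feature <- function(x, ...) tidy.error_report(x, ...)

#' One-row summary of an error report
#'
#' @param x an `error_report`.
#' @param resolution optional mm-per-pixel resolution (or range) used to
#'   add millimetre conversions of the median error.
#' @param ... ignored.
#' @return One-row tibble with totals, exclusion count and pixel-error
#'   summaries (mean and median are both reported since either is quoted
#'   in practice).
#' @method glance error_report
#' @export
glance.error_report <- function(x, resolution = NULL, ...) {
  inc <- x$errors$error[!x$errors$excluded]
  out <- tibble::tibble(
    n_total = x$n_total,
    n_included = length(inc),
    n_excluded = x$n_excluded,
    mean_error = if (length(inc)) mean(inc) else NA_real_,
    median_error = if (length(inc)) median(inc) else NA_real_,
    iqr_error = if (length(inc)) IQR(inc) else NA_real_,
    sd_error = if (length(inc) > 1) sd(inc) else NA_real_,
    cutoff = x$cutoff)
  if (!is.null(resolution)) {
    out$median_error_mm_min <- px_to_mm(out$median_error, min(resolution))
    out$median_error_mm_max <- px_to_mm(out$median_error, max(resolution))
  }
  out
}

#' Feature-sorted error distribution plot
#'
#' Box plots of the per-landmark pixel-error distributions, sorted by
#' increasing standard deviation and colored by the proximal-to-distal
#' group, mirroring the standard per-feature evaluation figure.
#'
#' @param object an `error_report`.
#' @param ... passed to [tidy.error_report()].
#' @return A ggplot object.
#' @method autoplot error_report
#' @export
autoplot.error_report <- function(object, ...) {
  per <- tidy.error_report(object, ...)
  dat <- dplyr::filter(object$errors, !.data$excluded)
  dat$landmark <- factor(dat$landmark, levels = rev(per$landmark))
  grp <- setNames(per$group, per$landmark)
  dat$group <- grp[as.character(dat$landmark)]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$error, y = .data$landmark,
                                    fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = "pixel error", y = NULL, fill = "group")
}

#' Mock predictor emulating a trained network's output
#'
#' Stands in for a pose-estimation network so the evaluation pipeline can
#' be exercised end to end: predictions are the ground truth plus
#' isotropic Gaussian noise; a `miss_rate` fraction of entries is
#' displaced to the position of a random *other* landmark in the same
#' frame (mislocation errors), and a `lowconf_rate` fraction receives a
#' confidence below 0.1 (as happens for occluded or out-of-frame
#' features). Seeded and deterministic.
#'
#' @param truth an `annotated_dataset` or annotation tibble.
#' @param noise_sd standard deviation of the positional noise (px).
#' @param miss_rate,lowconf_rate rates in `[0, 1]`.
#' @param seed integer seed.
#' @return Prediction tibble (`frame`, `landmark`, `x`, `y`,
#'   `confidence`).
#' @export
mock_predictor <- function(truth, noise_sd = 2, miss_rate = 0,
                           lowconf_rate = 0, seed = 1L) {
  if (noise_sd < 0) rlang::abort("noise_sd must be non-negative")
  if (miss_rate < 0 || miss_rate > 1 || lowconf_rate < 0 || lowconf_rate > 1)
    rlang::abort("rates must lie in [0, 1]")
  tt <- truth_table(truth)
  n <- nrow(tt)
  with_local_seed(seed, {
    x <- tt$x + rnorm(n, sd = noise_sd)
    y <- tt$y + rnorm(n, sd = noise_sd)
    conf <- runif(n, 0.5, 1)
    if (miss_rate > 0) {
      miss <- which(runif(n) < miss_rate)
      for (i in miss) {
        others <- which(tt$frame == tt$frame[i] &
                          tt$landmark != tt$landmark[i])
        if (length(others)) {
          j <- others[sample.int(length(others), 1)]
          x[i] <- tt$x[j] + rnorm(1, sd = noise_sd)
          y[i] <- tt$y[j] + rnorm(1, sd = noise_sd)
        }
      }
    }
    if (lowconf_rate > 0) {
      low <- runif(n) < lowconf_rate
      conf[low] <- runif(sum(low), 0, 0.0999)
    }
    tibble::tibble(frame = tt$frame, landmark = tt$landmark,
                   x = x, y = y, confidence = conf)
  })
}
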