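#' Run an evaluation design grid with a pluggable predictor
#'
#' Executes every row of a design grid (for example the 2 model types x 4
#' training fractions x 5 replicates = 40 runs of the transfer
#' experiment) against an arbitrary predictor and scores each run with
#' [evaluate_predictions()]. A predictor failure is recorded and the grid
#' continues; the failure count is part of the result.
#'
#' @param designs tibble with one row per run; a `seed` column is used if
#'   present, otherwise seeds are `1:nrow(designs)`.
#' @param predictor function `(truth, design)` returning a prediction
#'   tibble (`frame`, `landmark`, `x`, `y`, `confidence`); `design` is the
#'   run's one-row tibble.
#' @param truth an `annotated_dataset` (or annotation tibble) the
#'   predictions are scored against.
#' @param cutoff confidence cut-off passed to [evaluate_predictions()].
#' @return List of class `harness_result`: `results` (the design grid with
#'   the per-run [glance.error_report()] columns), `reports` (list of
#'   `error_report`s, NULL for failed runs), `failures` (tibble of run
#'   index and error message).
#' @export
run_experiment_harness <- function(designs, predictor, truth, cutoff = 0.10) {
  designs <- tibble::as_tibble(designs)
  if (!nrow(designs)) rlang::abort("design grid is empty")
  if (!is.function(predictor)) rlang::abort("predictor must be a function")
  reports <- vector("list", nrow(designs))
  glances <- vector("list", nrow(designs))
  fails <- list()
  for (i in seq_len(nrow(designs))) {
    design <- designs[i, ]
    res <- tryCatch({
      pred <- predictor(truth, design)
      evaluate_predictions(pred, truth, cutoff = cutoff)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        tibble::tibble(run = i, message = conditionMessage(res))
      glances[[i]] <- tibble::tibble(n_total = NA_integer_)
    } else {
      reports[[i]] <- res
      glances[[i]] <- glance(res)
    }
  }
  results <- dplyr::bind_cols(designs, dplyr::bind_rows(glances))
  structure(list(results = results, reports = reports,
                 failures = dplyr::bind_rows(fails)),
            class = "harness_result")
}

#' @export
print.harness_result <- function(x, ...) {
  cat("<harness_result> ", nrow(x$results), " runs, ",
      nrow(x$failures), " failures\n", sep = "")
  invisible(x)
}

#' Feature-by-model matrix of median errors
#'
#' Builds the blocked matrix consumed by [friedman_rank_test()]: one row
#' per body feature, one column per run, entries are per-feature median
#' pixel errors over included entries.
#'
#' @param result a `harness_result` (or a named list of `error_report`s).
#' @return Numeric matrix with landmark row names.
#' @export
harness_feature_matrix <- function(result) {
  reports <- if (inherits(result, "harness_result")) result$reports else result
  keep <- !vapply(reports, is.null, logical(1))
  reports <- reports[keep]
  if (!length(reports)) rlang::abort("no successful runs")
  cols <- lapply(reports, function(r) {
    per <- tidy(r)
    setNames(per$median, per$landmark)
  })
  features <- sort(unique(unlist(lapply(cols, names))))
  mat <- vapply(cols, function(v) v[features], numeric(length(features)))
  rownames(mat) <- features
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("model", seq_len(ncol(mat)))
  mat
}

#' Summary plot of a harness run
#'
#' Median pixel error per run, faceted by any grouping columns present
#' (e.g. model type vs. training fraction).
#'
#' @param object a `harness_result`.
#' @param x,color names of design columns to map (defaults try
#'   `fraction` and `model_type` when present).
#' @param ... ignored.
#' @return A ggplot object.
#' @method autoplot harness_result
#' @export
autoplot.harness_result <- function(object, x = NULL, color = NULL, ...) {
  df <- object$results
  if (is.null(x)) x <- if ("fraction" %in% names(df)) "fraction" else names(df)[1]
  if (is.null(color) && "model_type" %in% names(df)) color <- "model_type"
  aes <- if (is.null(color))
    ggplot2::aes(x = .data[[x]], y = .data$median_error)
  else
    ggplot2::aes(x = .data[[x]], y = .data$median_error,
                 color = .data[[color]])
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.01,
                                                            height = 0)) +
    ggplot2::stat_summary(fun = stats::median, geom = "line",
                          ggplot2::aes(group = if (is.null(color)) 1
                                       else .data[[color]])) +
    ggplot2::labs(x = x, y = "median pixel error")
}
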