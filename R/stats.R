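#' Friedman test across models
#'
#' Wrapper around the standard Friedman rank-sum chi-square (average ranks
#' for ties, k - 1 degrees of freedom) for a blocked design of error
#' summaries: one row per body feature (block), one column per model.
#' Used to test whether at least one model's median error differs.
#'
#' @param errors numeric matrix, rows = features (>= 2), columns =
#'   models (>= 2).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
friedman_rank_test <- function(errors) {
  errors <- as.matrix(errors)
  if (nrow(errors) < 2L || ncol(errors) < 2L)
    rlang::abort("need at least 2 features and 2 models")
  if (!all(is.finite(errors))) rlang::abort("errors must be finite")
  if (all(apply(errors, 1, function(r) diff(range(r)) == 0))) {
    # every block fully tied: no effect by construction
    return(tibble::tibble(statistic = 0, df = ncol(errors) - 1, p_value = 1))
  }
  ht <- stats::friedman.test(errors)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided paired comparison of matched error samples (e.g. per-feature
#' median errors of two models). Zero differences are dropped; the exact
#' null distribution is used for up to 25 non-zero pairs (falling back to
#' the normal approximation when ties make the exact distribution
#' unavailable), the normal approximation beyond that. If every
#' difference is zero the test is degenerate and `p_value = 1` is
#' returned with `all_zero = TRUE`.
#'
#' @param a,b equal-length numeric vectors (>= 5 pairs).
#' @return One-row tibble: `statistic` (V), `p_value`, `n_used`,
#'   `all_zero`.
#' @export
wilcoxon_matched_pairs <- function(a, b) {
  if (length(a) != length(b)) rlang::abort("samples must have equal length")
  if (length(a) < 5L) rlang::abort("need at least 5 matched pairs")
  d <- a - b
  nz <- d[d != 0]
  if (!length(nz))
    return(tibble::tibble(statistic = NA_real_, p_value = 1,
                          n_used = 0L, all_zero = TRUE))
  ht <- suppressWarnings(
    stats::wilcox.test(nz, exact = length(nz) <= 25, correct = TRUE))
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n_used = length(nz), all_zero = FALSE)
}

#' One-sided Mann-Whitney p-value from a rank-sum statistic
#'
#' Continuity-corrected normal approximation for a reported Mann-Whitney
#' U with group sizes `n1`, `n2`:
#' `z = (U + 0.5 - n1 n2 / 2) / sqrt(n1 n2 (n1 + n2 + 1) / 12)` and
#' `p = pnorm(z)` for U below its null mean (mirrored above it). This is
#' the variant that reproduces reported rank-sum p-values from published
#' (U, n1, n2) triples to three significant figures.
#'
#' @param U the Mann-Whitney statistic, in `[0, n1 * n2]`.
#' @param n1,n2 group sizes.
#' @return The one-sided p-value.
#' @export
mannwhitney_p <- function(U, n1, n2) {
  if (n1 < 1 || n2 < 1) rlang::abort("group sizes must be positive")
  if (U < 0 || U > n1 * n2)
    rlang::abort("U must lie between 0 and n1 * n2")
  mu <- n1 * n2 / 2
  sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  if (U <= mu) pnorm((U + 0.5 - mu) / sigma)
  else pnorm((mu - U + 0.5) / sigma)
}

#' Manual-annotation reduction from pre-training
#'
#' If a pre-trained model reaches the reference performance at training
#' fraction `fraction_pretrained` while the from-scratch model needs
#' `fraction_scratch`, pre-training reduces the manual annotation effort
#' by `100 * (1 - fraction_pretrained / fraction_scratch)` percent.
#'
#' @param fraction_pretrained,fraction_scratch training fractions in
#'   `(0, 1]` with `fraction_pretrained <= fraction_scratch`.
#' @return Percent reduction.
#' @export
annotation_reduction <- function(fraction_pretrained, fraction_scratch) {
  if (fraction_pretrained <= 0 || fraction_scratch > 1 ||
      fraction_pretrained > fraction_scratch)
    rlang::abort("need 0 < fraction_pretrained <= fraction_scratch <= 1")
  100 * (1 - fraction_pretrained / fraction_scratch)
}
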