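# Percept dominance-duration statistics: extraction from press timelines,
# unit-mean normalization per group, gamma fitting, rank-sum comparisons.

#' Extract percept dominance durations from a press timeline
#'
#' The duration of the percept reported at press k is
#' `time[k+1] - time[k]`. The final, block-truncated interval (no closing
#' press) is dropped, and so is the first reported percept of the block.
#'
#' @param timeline A [percept_timeline()] of button presses.
#' @return A tibble: `percept`, `onset_s` (press time), `duration_s`.
#'   Empty with fewer than 2 presses.
#' @export
extract_durations <- function(timeline) {
  stopifnot(inherits(timeline, "percept_timeline"))
  empty <- tibble::tibble(
    percept = character(0), onset_s = numeric(0), duration_s = numeric(0)
  )
  n <- nrow(timeline)
  if (n < 2) return(empty)
  out <- tibble::tibble(
    percept = timeline$percept[-n],
    onset_s = timeline$time_s[-n],
    duration_s = diff(timeline$time_s)
  )
  out[-1, ] # first reported percept excluded
}

#' Normalize durations to unit mean within groups
#'
#' Divides each duration by the mean of its group (by default the percept
#' type, matching per-block, per-percept normalization), so that normalized
#' histograms are comparable across subjects and conditions.
#'
#' @param durations A tibble with a `duration_s` column.
#' @param by Grouping columns.
#' @return The tibble with a `norm_duration` column added.
#' @export
normalize_durations <- function(durations, by = "percept") {
  durations |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(norm_duration = .data$duration_s / mean(.data$duration_s)) |>
    dplyr::ungroup()
}

#' Maximum-likelihood gamma fit of normalized dominance durations
#'
#' Dominance durations of bistable percepts, normalized to unit mean, are
#' well described by gamma distributions with shape close to 2; this fits
#' the shape and rate by maximum likelihood.
#'
#' @param x Positive durations (at least 10).
#' @param method `"mle"` (default) or `"mme"` (method of moments fallback).
#' @return List of class `gamma_fit`: `shape`, `rate`, `mean`, `n`.
#' @export
fit_gamma <- function(x, method = c("mle", "mme")) {
  method <- match.arg(method)
  if (length(x) < 10) stopf("Need at least 10 durations (have %d).", length(x))
  if (any(x <= 0)) stopf("Durations must be positive.")
  if (sd(x) == 0) stopf("Durations are constant; gamma fit is degenerate.")
  fit <- tryCatch(
    fitdistrplus::fitdist(as.numeric(x), "gamma", method = method),
    error = function(e) stopf("Gamma fit failed: %s", conditionMessage(e))
  )
  est <- fit$estimate
  structure(
    list(
      shape = unname(est["shape"]), rate = unname(est["rate"]),
      mean = unname(est["shape"] / est["rate"]), n = length(x)
    ),
    class = "gamma_fit"
  )
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf(
    "gamma fit: shape %.3f, rate %.3f (mean %.3f), n = %d\n",
    x$shape, x$rate, x$mean, x$n
  ))
  invisible(x)
}

# Two-sided rank-sum p value; exact enumeration for small tie-free samples,
# normal approximation with tie correction otherwise.
ranksum_p <- function(x, y) {
  has_ties <- anyDuplicated(c(x, y)) > 0
  small <- min(length(x), length(y)) < 20
  suppressWarnings(
    wilcox.test(x, y, exact = small && !has_ties, correct = TRUE)$p.value
  )
}

#' Compare two duration sets by a two-sided rank-sum test
#'
#' Wilcoxon rank-sum comparison of two sets of (normalized) durations, used
#' for condition and group comparisons. Small tie-free samples use the
#' exact null distribution; larger or tied samples the normal approximation
#' with tie correction.
#'
#' @param x,y Numeric duration vectors (nonempty).
#' @return The two-sided p value.
#' @export
compare_groups <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stopf("Both sets must be nonempty.")
  ranksum_p(x, y)
}
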