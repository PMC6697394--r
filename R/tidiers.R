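# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a site statistic map into its cluster table
#'
#' One row per significant-by-threshold cluster, across all sites, with the
#' cluster's time extent in ms relative to triplet onset and its
#' Monte-Carlo p value.
#'
#' @param x A `site_stat_map` from [aep_cluster_test()].
#' @param ... Unused.
#' @return A tibble: `site`, `area`, `start_ms`, `end_ms`, `sign`, `mass`,
#'   `p`, `q_reject`.
#' @method tidy site_stat_map
#' @export
tidy.site_stat_map <- function(x, ...) {
  cl <- attr(x, "clusters")
  fs <- 1000
  ms0 <- 0
  rows <- purrr::imap(cl, function(tbl, s) {
    if (is.null(tbl) || nrow(tbl) == 0) return(NULL)
    tibble::tibble(
      site = x$site[s], area = x$area[s],
      start_ms = (tbl$start - 1) / fs * 1000 + ms0,
      end_ms = tbl$end / fs * 1000 + ms0,
      sign = tbl$sign, mass = tbl$mass, p = tbl$p,
      q_reject = x$q_reject[s]
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname tidy.site_stat_map
#' @method glance site_stat_map
#' @export
glance.site_stat_map <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x),
    n_testable = sum(!is.na(x$p_site)),
    n_with_cluster = sum(x$n_clusters > 0, na.rm = TRUE),
    n_fdr_rejected = sum(x$q_reject),
    n_perm = attr(x, "n_perm"),
    q = attr(x, "q")
  )
}

#' Plot a site statistic map
#'
#' Per-site evidence (-log10 of the site p value) coloured by FDR decision,
#' grouped by cortical area: the machine form of a spatial significance map.
#'
#' @param object A `site_stat_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot site_stat_map
#' @export
autoplot.site_stat_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$neglogp <- -log10(df$p_site)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = factor(.data$site), y = .data$neglogp,
      fill = .data$q_reject
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(. ~ area, scales = "free_x", space = "free_x") +
    ggplot2::labs(
      x = "recording site", y = expression(-log[10] ~ p[site]),
      fill = "FDR significant"
    ) +
    ggplot2::theme_minimal()
}

#' Tidy and summarize a percept classifier
#'
#' `tidy()` returns the per-feature selection probabilities; `glance()` a
#' one-row accuracy summary.
#'
#' @param x A `percept_classifier` from [run_classification()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy percept_classifier
#' @export
tidy.percept_classifier <- function(x, ...) {
  x$feature_prob
}

#' @rdname tidy.percept_classifier
#' @method glance percept_classifier
#' @export
glance.percept_classifier <- function(x, ...) {
  tibble::tibble(
    n_rep = x$n_rep,
    mean_accuracy = mean(x$accuracy),
    median_accuracy = median(x$accuracy),
    sd_accuracy = sd(x$accuracy),
    median_d_star = median(x$d_star),
    n_map_sites = length(x$map_sites)
  )
}

#' Plot the accuracy distribution of a percept classifier
#'
#' Histogram of balanced test accuracies over repetitions, with the 0.5
#' chance level marked.
#'
#' @param object A `percept_classifier`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot percept_classifier
#' @export
autoplot.percept_classifier <- function(object, ...) {
  df <- tibble::tibble(accuracy = object$accuracy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "balanced test accuracy", y = "repetitions") +
    ggplot2::theme_minimal()
}

#' Plot a one-dimensional trial embedding
#'
#' Embedded coordinate of each trial against its time in the block, coloured
#' by reported percept.
#'
#' @param object A `trial_embedding` from [build_embedding()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trial_embedding
#' @export
autoplot.trial_embedding <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$onset_s, y = .data$coord, colour = .data$label)
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "trial onset (s)", y = "embedding coordinate",
      colour = "percept"
    ) +
    ggplot2::theme_minimal()
}

#' Tidy a gamma dominance-duration fit
#'
#' @param x A `gamma_fit` from [fit_gamma()].
#' @param ... Unused.
#' @return A one-row tibble: `shape`, `rate`, `mean`, `n`.
#' @method tidy gamma_fit
#' @export
tidy.gamma_fit <- function(x, ...) {
  tibble::tibble(shape = x$shape, rate = x$rate, mean = x$mean, n = x$n)
}
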