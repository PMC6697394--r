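# Pipeline configuration, the end-to-end driver, and plain-text containers
# for recordings and derived tables.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with its default: sampling
#' and filtering (1 kHz; 1.5-70 Hz LFP band; 2.2-2.7 Hz narrow-band stop
#' with 30 discarded spatial components; 4-SD artifact rejection), cluster
#' statistics (clusters of at least 20 ms, 10,000 permutations, pointwise
#' and cluster alpha 0.05, FDR at 1% across sites), classification (12
#' 50-ms bins, 4/5 training fraction, 100 repetitions, 0.3 selection-
#' probability threshold), high-gamma ERBP (70-150 Hz band, 1.5-40 Hz
#' smoothing), and embedding (2-s windows, kernel scale 0.2).
#'
#' @param fs Sampling rate after resampling (Hz).
#' @param band LFP band (Hz). @param stopband Narrow-band stop range (Hz).
#' @param n_discard Spatial components discarded by the narrow-band filter.
#' @param reject_sd Artifact rejection threshold (block SDs).
#' @param min_cluster_ms Minimum cluster extent (ms).
#' @param n_perm Permutations per site. @param alpha_point Pointwise alpha.
#' @param alpha_cluster Cluster significance level. @param q_fdr FDR level.
#' @param n_bins,bin_ms Feature binning. @param train_frac Training fraction.
#' @param n_rep Classifier repetitions. @param prob_thresh Feature map
#'   threshold. @param gamma_band,smooth_band ERBP bands (Hz).
#' @param embed_window Embedding epoch window `(pre, dur, post)` ms.
#' @param lambda Affinity kernel scale. @param rt Subject reaction time (s).
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 1000, band = c(1.5, 70),
                            stopband = c(2.2, 2.7), n_discard = 30,
                            reject_sd = 4, min_cluster_ms = 20,
                            n_perm = 10000, alpha_point = 0.05,
                            alpha_cluster = 0.05, q_fdr = 0.01,
                            n_bins = 12, bin_ms = 50, train_frac = 0.8,
                            n_rep = 100, prob_thresh = 0.3,
                            gamma_band = c(70, 150),
                            smooth_band = c(1.5, 40),
                            embed_window = c(700, 600, 700),
                            lambda = 0.2, rt = 0.6, seed = 1L) {
  cfg <- list(
    fs = fs, band = band, stopband = stopband, n_discard = n_discard,
    reject_sd = reject_sd, min_cluster_ms = min_cluster_ms,
    n_perm = n_perm, alpha_point = alpha_point,
    alpha_cluster = alpha_cluster, q_fdr = q_fdr, n_bins = n_bins,
    bin_ms = bin_ms, train_frac = train_frac, n_rep = n_rep,
    prob_thresh = prob_thresh, gamma_band = gamma_band,
    smooth_band = smooth_band, embed_window = embed_window,
    lambda = lambda, rt = rt, seed = as.integer(seed)
  )
  if (cfg$n_perm < 1) stopf("`n_perm` must be at least 1.")
  if (cfg$n_rep < 1) stopf("`n_rep` must be at least 1.")
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1) {
    stopf("`train_frac` must be in (0, 1).")
  }
  if (cfg$q_fdr <= 0 || cfg$q_fdr >= 1) stopf("`q_fdr` must be in (0, 1).")
  if (cfg$lambda <= 0) stopf("`lambda` must be positive.")
  if (cfg$n_bins * cfg$bin_ms != 600) {
    stopf("`n_bins` x `bin_ms` must cover the 600 ms triplet.")
  }
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Run the full analysis pipeline on one block
#'
#' Executes, in order: preprocessing to labelled triplet-locked epochs; the
#' AEP cluster-mass permutation test with FDR across sites; percept
#' classification; the high-gamma ERBP cluster test; the 2-s diffusion-map
#' embedding with maintenance and pre-switch rank-sum tests; and the
#' dominance-duration statistics. When no block is supplied a synthetic one
#' is generated from `synth` (seeded by the pipeline seed).
#'
#' @param config A [pipeline_config()].
#' @param block A [recording_block()] or [simulate_lfp_block()] result;
#'   `NULL` generates a synthetic block.
#' @param synth A [synthetic_config()] used when `block` is `NULL`.
#' @param out_dir Optional directory; results are written there as TSV/JSON
#'   (each file embeds the config hash and seed).
#' @param run Character subset of
#'   `c("aep", "classify", "erbp", "embed", "behavior")`.
#' @return A list of class `bistream_results` with elements `epochs`,
#'   `aep_map`, `classifier`, `erbp_map`, `embedding`, `maintenance`,
#'   `switch`, `durations`, `gamma_fit`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), block = NULL,
                         synth = NULL, out_dir = NULL,
                         run = c("aep", "classify", "erbp", "embed",
                                 "behavior")) {
  stopifnot(inherits(config, "pipeline_config"))
  run <- match.arg(run, several.ok = TRUE)
  if (is.null(block)) {
    if (is.null(synth)) synth <- synthetic_config(seed = config$seed)
    block <- simulate_lfp_block(synth)
  }
  if (inherits(block, "synthetic_block")) block <- block$block
  stopifnot(inherits(block, "recording_block"))
  if (is.null(block$timeline)) stopf("Missing input: percept timeline.")
  if (is.null(block$stim)) stopf("Missing input: stimulus timeline.")

  res <- list(config = config)

  ep <- preprocess_lfp(block,
    rt = config$rt, band = config$band,
    n_discard = config$n_discard, reject_sd = config$reject_sd
  )
  res$epochs <- ep

  if ("aep" %in% run) {
    res$aep_map <- aep_cluster_test(ep,
      n_perm = config$n_perm, min_len = config$min_cluster_ms,
      alpha = config$alpha_point, q = config$q_fdr, seed = config$seed
    )
  }
  if ("classify" %in% run) {
    ft <- bin_features(ep, bin_ms = config$bin_ms)
    res$classifier <- run_classification(ft,
      n_rep = config$n_rep, train_frac = config$train_frac,
      prob_thresh = config$prob_thresh, seed = config$seed
    )
  }
  if ("erbp" %in% run) {
    res$erbp_map <- erbp_cluster_test(block,
      rt = config$rt, n_perm = config$n_perm,
      min_len = config$min_cluster_ms, alpha = config$alpha_point,
      q = config$q_fdr, reject_sd = config$reject_sd, seed = config$seed
    )
  }
  if ("embed" %in% run) {
    pb <- resample_to_1khz(block)
    pb <- bandpass_lfp(pb, config$band)
    pb <- remove_narrowband_25(pb, config$n_discard)
    ep2 <- epoch_triplets(pb, config$embed_window)
    ep2 <- reject_trials(ep2, config$reject_sd)
    ep2 <- label_and_filter(ep2, block$timeline, config$rt)
    res$embedding <- build_embedding(ep2, lambda = config$lambda)
    res$maintenance <- maintenance_test(res$embedding, q = config$q_fdr)
    pre <- select_preswitch_trials(ep2, block$timeline)
    res$switch <- tryCatch(
      switch_test(build_embedding(pre, lambda = config$lambda)),
      error = function(e) NULL
    )
  }
  if ("behavior" %in% run) {
    res$durations <- normalize_durations(extract_durations(block$timeline))
    res$gamma_fit <- if (nrow(res$durations) >= 10) {
      fit_gamma(res$durations$norm_duration)
    }
  }
  class(res) <- "bistream_results"
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' @export
print.bistream_results <- function(x, ...) {
  cat("bistream pipeline results\n")
  if (!is.null(x$aep_map)) {
    cat(sprintf(
      "  AEP cluster test: %d/%d sites significant after FDR\n",
      sum(x$aep_map$q_reject), nrow(x$aep_map)
    ))
  }
  if (!is.null(x$classifier)) {
    cat(sprintf(
      "  classifier: median balanced accuracy %.3f\n",
      median(x$classifier$accuracy)
    ))
  }
  if (!is.null(x$erbp_map)) {
    cat(sprintf(
      "  ERBP cluster test: %d/%d sites significant after FDR\n",
      sum(x$erbp_map$q_reject), nrow(x$erbp_map)
    ))
  }
  if (!is.null(x$maintenance)) {
    pp <- x$maintenance$p[x$maintenance$subject == "pooled"]
    cat(sprintf("  embedding maintenance test (pooled): p = %.4g\n", pp))
  }
  if (!is.null(x$gamma_fit)) {
    cat(sprintf(
      "  dominance durations: gamma shape %.2f over %d percepts\n",
      x$gamma_fit$shape, x$gamma_fit$n
    ))
  }
  invisible(x)
}

# ---- plain-text containers ------------------------------------------------

tsv_header <- function(config) {
  sprintf("# config_hash=%s seed=%d", config_hash(config), config$seed)
}

write_tsv_with_header <- function(tbl, path, config = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(config)) writeLines(tsv_header(config), con)
  utils::write.table(tbl, con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write / read a recording block as plain-text files
#'
#' The block is stored as `<prefix>_data.tsv` (site x sample voltage matrix,
#' full precision), `<prefix>_meta.json` (sampling rate, site table,
#' stimulus parameters) and `<prefix>_events.tsv` (press/change events).
#' Reading validates the schema and errors naming any missing field.
#'
#' @param block A [recording_block()].
#' @param prefix Path prefix for the three files.
#' @return `write_block()` the prefix, invisibly; `read_block()` the
#'   reconstructed [recording_block()].
#' @export
write_block <- function(block, prefix) {
  stopifnot(inherits(block, "recording_block"))
  meta <- list(
    fs = block$fs,
    sites = block$sites,
    stim = if (!is.null(block$stim)) unclass(block$stim),
    block_dur = if (!is.null(block$timeline)) {
      attr(block$timeline, "block_dur")
    }
  )
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  dat <- apply(block$data, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = "\t")
  })
  writeLines(dat, paste0(prefix, "_data.tsv"))
  if (!is.null(block$timeline)) {
    write_events_tsv(paste0(prefix, "_events.tsv"),
      timeline = block$timeline
    )
  }
  invisible(prefix)
}

#' @rdname write_block
#' @export
read_block <- function(prefix) {
  meta_path <- paste0(prefix, "_meta.json")
  if (!file.exists(meta_path)) stopf("Missing file: %s", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("fs", "sites")) {
    if (is.null(meta[[field]])) {
      stopf("Schema error in %s: missing field `%s`.", meta_path, field)
    }
  }
  lines <- readLines(paste0(prefix, "_data.tsv"))
  data <- do.call(rbind, lapply(strsplit(lines, "\t"), as.numeric))
  stim <- if (!is.null(meta$stim)) {
    triplet_stimulus(
      f_b = meta$stim$f_b, df = meta$stim$df,
      n_triplets = meta$stim$n_triplets, tone_dur = meta$stim$tone_dur,
      intra_gap = meta$stim$intra_gap, inter_gap = meta$stim$inter_gap
    )
  }
  timeline <- NULL
  ev_path <- paste0(prefix, "_events.tsv")
  if (file.exists(ev_path)) {
    ev <- read_events_tsv(ev_path)
    presses <- ev[ev$kind == "press", ]
    changes <- ev$onset_s[ev$kind == "change"]
    timeline <- percept_timeline(
      presses$onset_s, presses$value,
      block_dur = meta$block_dur %||% (ncol(data) / meta$fs),
      change_times = if (length(changes)) changes
    )
  }
  recording_block(data, meta$fs, tibble::as_tibble(meta$sites),
    stim = stim, timeline = timeline
  )
}

#' Write pipeline results as TSV/JSON files
#'
#' Writes the site statistic map, classifier feature probabilities and
#' accuracy summary, ERBP site map, embedding table with its statistics,
#' and duration table into `out_dir`. Every file embeds the configuration
#' hash and seed.
#'
#' @param res A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(res, out_dir) {
  stopifnot(inherits(res, "bistream_results"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- res$config
  p <- function(f) file.path(out_dir, f)
  if (!is.null(res$aep_map)) {
    write_tsv_with_header(tibble::as_tibble(res$aep_map), p("aep_sites.tsv"),
                          cfg)
  }
  if (!is.null(res$erbp_map)) {
    write_tsv_with_header(tibble::as_tibble(res$erbp_map),
                          p("erbp_sites.tsv"), cfg)
  }
  if (!is.null(res$classifier)) {
    write_tsv_with_header(res$classifier$feature_prob,
                          p("feature_probability.tsv"), cfg)
    jsonlite::write_json(
      list(
        config_hash = config_hash(cfg), seed = cfg$seed,
        mean_accuracy = mean(res$classifier$accuracy),
        median_accuracy = median(res$classifier$accuracy),
        accuracy = res$classifier$accuracy,
        map_sites = res$classifier$map_sites
      ),
      p("classifier.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(res$embedding)) {
    write_tsv_with_header(tibble::as_tibble(res$embedding),
                          p("embedding.tsv"), cfg)
    stats <- list(
      config_hash = config_hash(cfg), seed = cfg$seed,
      maintenance = res$maintenance, switch = res$switch
    )
    jsonlite::write_json(stats, p("embedding_stats.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  if (!is.null(res$durations)) {
    write_tsv_with_header(res$durations, p("durations.tsv"), cfg)
  }
  invisible(out_dir)
}
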