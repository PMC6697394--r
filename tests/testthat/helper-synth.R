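# Shared fixture builders: everything is generated in code at test time.

# Small synthetic block: `n_triplets` triplets, few sites, strong defaults.
mini_block <- function(n_triplets = 60, n_sites = 6, effect_sites = c(1, 2),
                       effect_amp = 40, noise_sd = 20, mean_dur = 6,
                       rt_mean = 0.4, seed = 42, ...) {
  stim <- triplet_stimulus(n_triplets = n_triplets)
  cfg <- synthetic_config(
    n_sites = n_sites, effect_sites = effect_sites,
    effect_amp = effect_amp, noise_sd = noise_sd,
    percept_mean_dur = c("1-stream" = mean_dur, "2-stream" = mean_dur),
    rt_mean = rt_mean, seed = seed, ...
  )
  simulate_lfp_block(cfg, stim)
}

# Wrap a trial x site x time array (plus labels) into a labeled_epochs
# object so statistical operations can be unit-tested in isolation.
epochs_from_array <- function(arr, labels, fs = 1000,
                              window = c(0, dim(arr)[3] / fs * 1000, 0),
                              areas = NULL) {
  d <- dim(arr)
  if (is.null(areas)) areas <- rep("HGPM", d[2])
  structure(
    list(
      trials = arr,
      labels = labels,
      kept = matrix(TRUE, d[1], d[2]),
      trial_onsets = (seq_len(d[1]) - 1) * 0.6,
      window = window, fs = fs,
      sites = tibble::tibble(
        site = seq_len(d[2]), area = areas,
        x = NA_real_, y = NA_real_, z = NA_real_
      ),
      triplet_dur = 0.6
    ),
    class = "labeled_epochs"
  )
}

# Two-class Gaussian epochs with an optional mean offset on a sample range.
two_class_epochs <- function(n_per_class = 30, n_time = 200, n_sites = 1,
                             offset = 0, offset_range = 81:130, sd = 1,
                             seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    arr <- array(rnorm(n * n_sites * n_time, sd = sd),
      dim = c(n, n_sites, n_time)
    )
    labels <- rep(c("1-stream", "2-stream"), each = n_per_class)
    if (offset != 0) {
      arr[labels == "2-stream", , offset_range] <-
        arr[labels == "2-stream", , offset_range] + offset
    }
    epochs_from_array(arr, labels)
  })
}
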