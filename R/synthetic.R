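# Synthetic recordings and behaviour with the statistical structure the
# analysis pipeline assumes: tone-locked evoked components whose latency and
# width depend on the cortical area of the site, an additive percept effect
# concentrated in a window after tone-B onset, 1/f background noise, a
# narrow-band ~2.5 Hz interference shared across sites, occasional
# high-amplitude artifacts, and gamma-distributed percept dominance
# durations reported with a reaction-time delay.

# Per-area evoked-component parameterization: core auditory cortex (HGPM)
# responds with short latency, large amplitude and narrow peaks; downstream
# areas (STG, MTG) with longer latencies and broader peaks; non-auditory
# sites ("other") with small, late, diffuse responses.
area_params <- function() {
  tibble::tribble(
    ~area,   ~lat_ms, ~sigma_ms, ~freq_hz, ~amp_scale,
    "HGPM",   30,      20,        10,       1.00,
    "HGAL",   50,      30,         8,       0.70,
    "PT",     40,      25,         9,       0.80,
    "PP",     55,      30,         8,       0.60,
    "STG",    80,      40,         6,       0.50,
    "MTG",    80,      45,         6,       0.40,
    "other",  90,      50,         5,       0.15
  )
}

#' Configuration of the synthetic recording generator
#'
#' Defaults emulate the experimental conditions the pipeline targets:
#' 1 kHz sampling, percept dominance durations gamma-distributed with shape 2
#' and means of roughly 23 s (1-stream) and 33 s (2-stream), a percept effect
#' of 10 uV concentrated 60-130 ms after tone-B onset (observed effects span
#' roughly 4-18 uV), 1/f background noise, a 2.5 Hz interference component
#' shared across sites, and occasional high-amplitude artifact transients.
#'
#' @param n_sites Number of recording sites.
#' @param site_areas Per-site area label from
#'   `c("HGPM","HGAL","PT","PP","STG","MTG","other")`; recycled round-robin
#'   from that list if `NULL`.
#' @param fs Sampling rate (Hz).
#' @param effect_sites Integer indices of sites carrying a percept effect;
#'   default: all auditory (non-"other") sites.
#' @param effect_window `(t0, t1)` in ms after tone-B onset where the percept
#'   effect lives.
#' @param effect_amp Peak AEP difference between percepts at effect sites (uV).
#' @param evoked_amp Peak amplitude of the evoked component at HGPM sites (uV).
#' @param noise_sd Total background-noise SD (uV); split between pink and
#'   white components.
#' @param pink_exponent Spectral exponent of the 1/f^a noise component.
#' @param line_freq,line_amp Frequency (Hz) and amplitude (uV) of the
#'   narrow-band interference shared across sites.
#' @param artifact_rate Expected artifact transients per minute per site.
#' @param percept_mean_dur Named mean dominance durations (s) for
#'   `"1-stream"` and `"2-stream"`.
#' @param gamma_shape Shape of the gamma dominance-duration distribution.
#' @param rt_mean Mean reaction time (s) between a perceptual switch and the
#'   button press reporting it.
#' @param gamma_burst_amp Amplitude (uV) of a high-gamma (100 Hz) burst after
#'   tone B; 0 disables it.
#' @param gamma_effect_amp Percept-dependent difference in high-gamma burst
#'   amplitude at effect sites (uV); 0 reproduces the situation in which the
#'   percept modulates low-frequency potentials but not high-gamma power.
#' @param seed Integer seed; all randomness in the generator flows through it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 16, site_areas = NULL, fs = 1000,
                             effect_sites = NULL,
                             effect_window = c(60, 130),
                             effect_amp = 10, evoked_amp = 40,
                             noise_sd = 20, pink_exponent = 1,
                             line_freq = 2.5, line_amp = 5,
                             artifact_rate = 1,
                             percept_mean_dur = c(
                               "1-stream" = 22.9, "2-stream" = 32.6
                             ),
                             gamma_shape = 2, rt_mean = 0.6,
                             gamma_burst_amp = 0, gamma_effect_amp = 0,
                             seed = 1L) {
  canonical <- area_params()$area
  if (is.null(site_areas)) {
    site_areas <- rep(setdiff(canonical, "other"),
      length.out = n_sites
    )
  }
  bad <- setdiff(unique(site_areas), canonical)
  if (length(bad)) stopf("Unknown area label: %s", bad[1])
  if (length(site_areas) != n_sites) {
    stopf("`site_areas` must have length `n_sites`.")
  }
  if (is.null(effect_sites)) effect_sites <- which(site_areas != "other")
  if (any(effect_window < 0) || diff(effect_window) <= 0) {
    stopf("`effect_window` must be an increasing pair of nonnegative ms.")
  }
  stopifnot(
    fs > 0, noise_sd >= 0, artifact_rate >= 0,
    all(percept_mean_dur > 0), gamma_shape > 0, rt_mean >= 0
  )
  structure(
    list(
      n_sites = as.integer(n_sites), site_areas = site_areas, fs = fs,
      effect_sites = as.integer(effect_sites),
      effect_window = effect_window, effect_amp = effect_amp,
      evoked_amp = evoked_amp, noise_sd = noise_sd,
      pink_exponent = pink_exponent, line_freq = line_freq,
      line_amp = line_amp, artifact_rate = artifact_rate,
      percept_mean_dur = percept_mean_dur, gamma_shape = gamma_shape,
      rt_mean = rt_mean, gamma_burst_amp = gamma_burst_amp,
      gamma_effect_amp = gamma_effect_amp, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Simulate a sequence of alternating percept dominance durations
#'
#' Dominance durations are drawn from gamma distributions with the
#' configured shape and per-percept mean, alternating between 1-stream and
#' 2-stream until the block ends. The returned timeline holds the *true*
#' percept onsets (no reaction-time delay); the first percept starts at t = 0
#' and is recorded in the `initial_percept` attribute rather than as an
#' event, since the subject only reports from the first switch on.
#'
#' @param cfg A [synthetic_config()].
#' @param block_dur Block duration (s).
#' @param seed Seed; defaults to the seed in `cfg`.
#' @return A [percept_timeline()] of true switch times with attribute
#'   `initial_percept`.
#' @export
simulate_percept_sequence <- function(cfg, block_dur, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"), block_dur > 0)
  with_seed(seed, {
    percepts <- names(cfg$percept_mean_dur)
    cur <- sample(percepts, 1L)
    initial <- cur
    t <- 0
    times <- numeric(0)
    labs <- character(0)
    repeat {
      dur <- rgamma(1,
        shape = cfg$gamma_shape,
        scale = cfg$percept_mean_dur[[cur]] / cfg$gamma_shape
      )
      t <- t + dur
      if (t >= block_dur) break
      cur <- setdiff(percepts, cur)
      times <- c(times, t)
      labs <- c(labs, cur)
    }
    tl <- percept_timeline(times, labs, block_dur)
    attr(tl, "initial_percept") <- initial
    tl
  })
}

#' Delay percept onsets by a simulated reaction time
#'
#' Each true percept onset is delayed by a nonnegative latency drawn from a
#' normal distribution with mean `rt_mean` (SD `rt_mean / 3`), truncated at
#' zero by resampling; delays that would reorder presses are also resampled.
#'
#' @param timeline A true-onset [percept_timeline()].
#' @param rt_mean Mean reaction time (s); 0 returns the timeline unchanged.
#' @param seed Integer seed.
#' @return A [percept_timeline()] of button-press times (attributes
#'   preserved).
#' @export
simulate_button_presses <- function(timeline, rt_mean, seed = 1L) {
  stopifnot(inherits(timeline, "percept_timeline"), rt_mean >= 0)
  if (rt_mean == 0 || nrow(timeline) == 0) return(timeline)
  with_seed(seed, {
    n <- nrow(timeline)
    draw <- function(k) {
      d <- rnorm(k, mean = rt_mean, sd = rt_mean / 3)
      while (any(d < 0)) d[d < 0] <- rnorm(sum(d < 0), rt_mean, rt_mean / 3)
      d
    }
    times <- timeline$time_s + draw(n)
    for (i in seq_len(200)) {
      if (!is.unsorted(times, strictly = TRUE)) break
      bad <- which(diff(times) <= 0) + 1L
      times[bad] <- timeline$time_s[bad] + draw(length(bad))
    }
    out <- percept_timeline(times, timeline$percept,
      attr(timeline, "block_dur"),
      change_times = attr(timeline, "change_times")
    )
    attr(out, "initial_percept") <- attr(timeline, "initial_percept")
    out
  })
}

# Gabor-like evoked kernel for one tone in a given area: damped sinusoid
# under a Gaussian envelope centred `lat_ms` after tone onset. Peak value 1.
evoked_kernel <- function(lat_ms, sigma_ms, freq_hz, fs) {
  t <- seq(0, (lat_ms + 4 * sigma_ms) / 1000, by = 1 / fs)
  env <- exp(-((t - lat_ms / 1000)^2) / (2 * (sigma_ms / 1000)^2))
  k <- env * sin(2 * pi * freq_hz * (t - lat_ms / 1000) + pi / 2)
  k / max(abs(k))
}

# Raised-cosine bump spanning [w0, w1] ms; peak 1. Carrier of the additive
# percept effect and of gamma-burst envelopes.
hann_bump <- function(w0_ms, w1_ms, fs) {
  n <- max(2L, round((w1_ms - w0_ms) / 1000 * fs))
  0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))
}

add_at <- function(x, kernel, idx) {
  # adds `kernel` into x starting at sample idx (1-based), clipping at ends
  n <- length(x)
  keep <- idx >= 1 - length(kernel) + 1 & idx <= n
  for (i in idx[keep]) {
    j <- i:min(n, i + length(kernel) - 1L)
    x[j] <- x[j] + kernel[seq_along(j)]
  }
  x
}

#' Simulate a continuous multi-site recording block
#'
#' Builds a recording in which every tone onset adds an area-specific evoked
#' component, effect sites additionally carry a percept-dependent additive
#' component after tone-B onset, and the background is 1/f-plus-white noise
#' with optional narrow-band interference and Poisson-placed high-amplitude
#' bipolar artifact transients (50 ms, 8-12x the noise SD, so they reliably
#' trip a 4-SD rejection rule). The percept effect is split symmetrically:
#' +effect/2 on 2-stream trials and -effect/2 on 1-stream trials, so the AEP
#' difference between percept classes peaks at `effect_amp`.
#'
#' @param cfg A [synthetic_config()].
#' @param stim A [triplet_stimulus()]; its duration defines the block.
#' @param timeline Optional true-onset percept timeline (from
#'   [simulate_percept_sequence()]); simulated from `cfg` if `NULL`.
#' @param seed Seed; defaults to the seed in `cfg`.
#' @return A list of class `synthetic_block` with elements `block`
#'   (a [recording_block()]), `timeline` (button presses, RT-delayed),
#'   `true_timeline`, `ground_truth` (tibble: trial, onset_s, true_percept),
#'   `effect_sites`, `effect_window`.
#' @export
simulate_lfp_block <- function(cfg, stim = triplet_stimulus(),
                               timeline = NULL, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  fs <- cfg$fs
  block_dur <- stim$n_triplets * stim$triplet_dur
  n <- round(block_dur * fs)
  tones <- build_triplet_sequence(stim)
  pars <- area_params()

  with_seed(seed, {
    if (is.null(timeline)) {
      timeline <- simulate_percept_sequence(cfg, block_dur,
        seed = sample.int(.Machine$integer.max, 1)
      )
    }
    stopifnot(inherits(timeline, "percept_timeline"))

    # True percept of each triplet: label at triplet onset from the true
    # timeline, falling back to the initial percept before the first switch.
    trip_onsets <- (seq_len(stim$n_triplets) - 1L) * stim$triplet_dur
    truth <- percept_label_at(timeline, trip_onsets)
    init <- attr(timeline, "initial_percept")
    if (!is.null(init)) truth[truth == "unlabeled"] <- init

    tone_idx <- round(tones$onset_s * fs) + 1L
    b_rows <- tones$tone == "B"
    b_idx <- tone_idx[b_rows]
    b_truth <- truth[tones$triplet[b_rows]]
    sgn <- ifelse(b_truth == "2-stream", 0.5, -0.5)

    # Deterministic per-area template (identical for sites sharing an area).
    templates <- list()
    for (a in unique(cfg$site_areas)) {
      p <- pars[pars$area == a, ]
      kern <- evoked_kernel(p$lat_ms, p$sigma_ms, p$freq_hz, fs) *
        cfg$evoked_amp * p$amp_scale
      templates[[a]] <- add_at(numeric(n), kern, tone_idx)
    }

    # Additive percept effect after tone B (shared by all effect sites).
    effect_sig <- numeric(n)
    if (cfg$effect_amp != 0) {
      bump <- hann_bump(cfg$effect_window[1], cfg$effect_window[2], fs) *
        cfg$effect_amp
      off <- round(cfg$effect_window[1] / 1000 * fs)
      for (k in seq_along(b_idx)) {
        i <- b_idx[k] + off
        j <- i:min(n, i + length(bump) - 1L)
        effect_sig[j] <- effect_sig[j] + sgn[k] * bump[seq_along(j)]
      }
    }

    # Optional high-gamma burst after tone B (envelope 30-80 ms post-B),
    # with a percept-dependent amplitude difference at effect sites.
    gamma_base <- gamma_eff <- NULL
    if (cfg$gamma_burst_amp > 0 || cfg$gamma_effect_amp != 0) {
      genv <- hann_bump(30, 80, fs)
      tt <- seq_along(genv) / fs
      carrier <- sin(2 * pi * 100 * tt)
      gk <- genv * carrier
      off <- round(30 / 1000 * fs)
      gamma_base <- gamma_eff <- numeric(n)
      for (k in seq_along(b_idx)) {
        i <- b_idx[k] + off
        j <- i:min(n, i + length(gk) - 1L)
        gamma_base[j] <- gamma_base[j] + cfg$gamma_burst_amp * gk[seq_along(j)]
        gamma_eff[j] <- gamma_eff[j] +
          sgn[k] * cfg$gamma_effect_amp * gk[seq_along(j)]
      }
    }

    line <- if (cfg$line_amp > 0) {
      cfg$line_amp * sin(2 * pi * cfg$line_freq * (seq_len(n) - 1) / fs +
        runif(1, 0, 2 * pi))
    } else {
      numeric(n)
    }
    line_gain <- runif(cfg$n_sites, 0.5, 1.5)

    data <- matrix(0, nrow = cfg$n_sites, ncol = n)
    for (s in seq_len(cfg$n_sites)) {
      x <- templates[[cfg$site_areas[s]]]
      if (s %in% cfg$effect_sites) x <- x + effect_sig
      if (!is.null(gamma_base)) {
        x <- x + gamma_base
        if (s %in% cfg$effect_sites) x <- x + gamma_eff
      }
      if (cfg$noise_sd > 0) {
        x <- x + cfg$noise_sd / sqrt(2) *
          (pink_noise(n, cfg$pink_exponent) + rnorm(n))
      }
      x <- x + line * line_gain[s]
      n_art <- rpois(1, cfg$artifact_rate * block_dur / 60)
      if (n_art > 0 && cfg$noise_sd > 0) {
        art_len <- round(0.05 * fs)
        shape <- sin(2 * pi * seq_len(art_len) / art_len)
        for (a in seq_len(n_art)) {
          amp <- runif(1, 8, 12) * cfg$noise_sd * sample(c(-1, 1), 1)
          x <- add_at(x, amp * shape, sample.int(n - art_len, 1))
        }
      }
      data[s, ] <- x
    }

    presses <- simulate_button_presses(timeline, cfg$rt_mean,
      seed = sample.int(.Machine$integer.max, 1)
    )

    sites <- tibble::tibble(
      site = seq_len(cfg$n_sites), area = cfg$site_areas,
      x = NA_real_, y = NA_real_, z = NA_real_
    )
    block <- recording_block(data, fs, sites,
      stim = stim, timeline = presses
    )
    structure(
      list(
        block = block, timeline = presses, true_timeline = timeline,
        ground_truth = tibble::tibble(
          trial = seq_len(stim$n_triplets),
          onset_s = trip_onsets, true_percept = truth
        ),
        effect_sites = cfg$effect_sites,
        effect_window = cfg$effect_window
      ),
      class = "synthetic_block"
    )
  })
}
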