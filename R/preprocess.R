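# Continuous-recording container and the preprocessing chain that turns it
# into labeled, artifact-screened, triplet-locked trials.

#' Construct a continuous multi-site recording block
#'
#' @param data Numeric site x sample voltage matrix (uV).
#' @param fs Sampling rate (Hz).
#' @param sites Per-site metadata tibble with at least columns `site` and
#'   `area`; optional MNI `x`, `y`, `z`.
#' @param stim Optional [triplet_stimulus()] giving the stimulus timeline.
#' @param timeline Optional [percept_timeline()] of button presses.
#' @return An object of class `recording_block`.
#' @export
recording_block <- function(data, fs, sites, stim = NULL, timeline = NULL) {
  data <- as.matrix(data)
  if (fs <= 0) stopf("`fs` must be positive.")
  sites <- tibble::as_tibble(sites)
  if (nrow(sites) != nrow(data)) {
    stopf(
      "`sites` has %d rows but `data` has %d site rows.",
      nrow(sites), nrow(data)
    )
  }
  if (!all(c("site", "area") %in% names(sites))) {
    stopf("`sites` needs columns `site` and `area`.")
  }
  structure(
    list(data = data, fs = fs, sites = sites, stim = stim,
         timeline = timeline),
    class = "recording_block"
  )
}

#' @export
print.recording_block <- function(x, ...) {
  cat(sprintf(
    "recording_block: %d sites x %d samples at %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  invisible(x)
}

block_duration <- function(block) ncol(block$data) / block$fs

#' Resample a recording block to 1 kHz
#'
#' Applies an anti-alias zero-phase low-pass (4th-order Butterworth at
#' 450 Hz, forward-backward) and resamples each site onto the uniform 1 kHz
#' grid by interpolation. Acquisition rates such as 2034.5 or 2000 Hz are
#' both handled; a block already at 1 kHz is returned unchanged.
#'
#' @param block A [recording_block()] with `fs >= 1000`.
#' @return The block resampled to `fs = 1000`.
#' @export
resample_to_1khz <- function(block) {
  stopifnot(inherits(block, "recording_block"))
  if (block$fs < 1000) stopf("Cannot upsample: fs = %g < 1000 Hz.", block$fs)
  if (block$fs == 1000) return(block)
  n <- ncol(block$data)
  t_in <- (seq_len(n) - 1) / block$fs
  t_out <- seq(0, t_in[n], by = 1 / 1000)
  out <- matrix(0, nrow = nrow(block$data), ncol = length(t_out))
  for (s in seq_len(nrow(block$data))) {
    x <- butter_filtfilt(block$data[s, ], block$fs, 450, type = "low")
    out[s, ] <- approx(t_in, x, xout = t_out)$y
  }
  block$data <- out
  block$fs <- 1000
  block
}

#' Band-pass filter a block to the LFP range
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass, by default
#' 1.5-70 Hz; removes DC and drift along with high-frequency content.
#'
#' @param block A [recording_block()].
#' @param band Pass band in Hz.
#' @return The filtered block.
#' @export
bandpass_lfp <- function(block, band = c(1.5, 70)) {
  stopifnot(inherits(block, "recording_block"))
  for (s in seq_len(nrow(block$data))) {
    block$data[s, ] <- butter_filtfilt(block$data[s, ], block$fs, band)
  }
  block
}

#' Remove narrow-band interference near 2.5 Hz by spatial and temporal filters
#'
#' Eliminates frequency components in `band` (default 2.2-2.7 Hz) in two
#' steps. First, the band-limited component of the data is extracted
#' (zero-phase FFT band selection) and the singular value decomposition of
#' its normalized spatial correlation matrix is computed; the reconstruction
#' of the first `min(n_discard, n_sites - 1)` spatial components is
#' subtracted from the broadband signal, removing interference shared across
#' sites. Second, any remaining energy in the band is removed per site by a
#' zero-phase temporal notch. Only the narrow-band component is ever
#' subtracted, so broadband signal outside the band is untouched.
#'
#' @param block A [recording_block()] with at least 2 sites.
#' @param n_discard Number of spatial components to discard (capped at
#'   `n_sites - 1`, with a warning).
#' @param band Stop band in Hz.
#' @return The filtered block.
#' @export
remove_narrowband_25 <- function(block, n_discard = 30, band = c(2.2, 2.7)) {
  stopifnot(inherits(block, "recording_block"))
  n_sites <- nrow(block$data)
  if (n_sites < 2) stopf("Spatial filtering needs at least 2 sites.")
  if (n_discard >= n_sites) {
    warnf(
      "`n_discard` = %d >= %d sites; capped at %d spatial components.",
      n_discard, n_sites, n_sites - 1
    )
    n_discard <- n_sites - 1L
  }
  bandc <- t(apply(
    block$data, 1,
    function(x) fft_band_component(x, block$fs, band[1], band[2])
  ))
  sds <- apply(bandc, 1, sd)
  if (any(sds > 0)) {
    # Normalized (unit-diagonal) spatial correlation of the band component;
    # zero-variance sites contribute nothing.
    ok <- sds > 0
    bn <- bandc[ok, , drop = FALSE] / sds[ok]
    cmat <- tcrossprod(bn) / ncol(bn)
    dec <- svd(cmat)
    d <- min(n_discard, sum(ok))
    u <- dec$u[, seq_len(d), drop = FALSE]
    recon <- u %*% (t(u) %*% bn) * sds[ok]
    block$data[ok, ] <- block$data[ok, ] - recon
  }
  # Temporal notch of any residual band energy, per site.
  for (s in seq_len(n_sites)) {
    block$data[s, ] <- block$data[s, ] -
      fft_band_component(block$data[s, ], block$fs, band[1], band[2])
  }
  block
}

#' Cut a block into triplet-locked trials
#'
#' One trial per stimulus triplet, time-locked to the triplet onset. The
#' default window `(0, 600, 0)` ms yields the 600 ms triplet epoch; the
#' embedding analysis uses `(700, 600, 700)` ms, a 2 s window centred on the
#' triplet. Trials whose window extends past the recording are dropped (and
#' listed in the `dropped` attribute).
#'
#' @param block A [recording_block()] whose `stim` timeline is present.
#' @param window `(pre, dur, post)` in ms.
#' @return An object of class `labeled_epochs`: list with `trials`
#'   (trial x site x time array), `labels` (all `NA` until
#'   [label_and_filter()]), `kept` (trial x site logical), `trial_onsets`,
#'   `window`, `fs`, `sites`.
#' @export
epoch_triplets <- function(block, window = c(0, 600, 0)) {
  stopifnot(inherits(block, "recording_block"))
  if (is.null(block$stim)) stopf("Block carries no stimulus timeline.")
  stim <- block$stim
  fs <- block$fs
  onsets <- (seq_len(stim$n_triplets) - 1L) * stim$triplet_dur
  pre <- window[1] / 1000
  dur <- window[2] / 1000
  post <- window[3] / 1000
  len <- round((pre + dur + post) * fs)
  n_samp <- ncol(block$data)
  start_idx <- round((onsets - pre) * fs) + 1L
  ok <- start_idx >= 1L & start_idx + len - 1L <= n_samp
  if (!any(ok)) stopf("No trial fits the recording with this window.")
  kept_onsets <- onsets[ok]
  idx <- start_idx[ok]
  n_trials <- length(idx)
  n_sites <- nrow(block$data)
  trials <- array(0, dim = c(n_trials, n_sites, len))
  for (i in seq_len(n_trials)) {
    trials[i, , ] <- block$data[, idx[i]:(idx[i] + len - 1L)]
  }
  structure(
    list(
      trials = trials,
      labels = rep(NA_character_, n_trials),
      kept = matrix(TRUE, n_trials, n_sites),
      trial_onsets = kept_onsets,
      window = window, fs = fs, sites = block$sites,
      triplet_dur = stim$triplet_dur
    ),
    dropped = which(!ok),
    class = "labeled_epochs"
  )
}

#' @export
print.labeled_epochs <- function(x, ...) {
  d <- dim(x$trials)
  lab <- table(x$labels, useNA = "ifany")
  cat(sprintf(
    "labeled_epochs: %d trials x %d sites x %d samples (window %d+%d+%d ms)\n",
    d[1], d[2], d[3], x$window[1], x$window[2], x$window[3]
  ))
  cat("  labels:", paste(sprintf(
    "%s=%d", ifelse(is.na(names(lab)), "NA", names(lab)), as.integer(lab)
  ), collapse = ", "), "\n")
  invisible(x)
}

#' Mask trials containing high-amplitude artifacts
#'
#' For each site, a trial is rejected if any sample deviates from the
#' within-block mean by more than `n_sd` (default 4) within-block standard
#' deviations. The criterion is applied per acquisition channel, so a trial
#' may be retained at some sites and rejected at others. Block statistics
#' are always computed over all trials, so the operation is idempotent.
#'
#' @param ep A [epoch_triplets()] result.
#' @param n_sd Rejection threshold in block SDs.
#' @return `ep` with its `kept` mask updated.
#' @export
reject_trials <- function(ep, n_sd = 4) {
  stopifnot(inherits(ep, "labeled_epochs"))
  n_sites <- dim(ep$trials)[2]
  for (s in seq_len(n_sites)) {
    x <- ep$trials[, s, , drop = TRUE]
    mu <- mean(x)
    sdev <- sd(as.vector(x))
    if (sdev == 0) {
      ep$kept[, s] <- TRUE
      next
    }
    ep$kept[, s] <- apply(abs(x - mu) <= n_sd * sdev, 1, all)
  }
  ep
}

# Epochs (in units of trials) to discard before each press for a given mean
# reaction time: at least 2, more for slower responders.
preswitch_exclusion_count <- function(rt, epoch_dur = 0.6) {
  max(2L, as.integer(ceiling(rt / epoch_dur - 1e-9)))
}

#' Label trials by reported percept and apply behavioural exclusions
#'
#' Labels each trial with the percept reported at its onset. Excluded (label
#' `NA`): trials before the first button press; the `k` trials immediately
#' preceding each press, with `k = max(2, ceiling(rt / 0.6))`, accounting for
#' the subject's reaction time; and, when the timeline carries stimulus
#' change times (control blocks), trials between a stimulus change and the
#' behavioural response to it.
#'
#' @param ep A [labeled_epochs()] object.
#' @param timeline The button-press [percept_timeline()].
#' @param rt Subject mean reaction time (s).
#' @return `ep` with `labels` filled in (`NA` for excluded trials).
#' @export
label_and_filter <- function(ep, timeline, rt = 0) {
  stopifnot(inherits(ep, "labeled_epochs"), rt >= 0)
  onsets <- ep$trial_onsets
  labs <- percept_label_at(timeline, onsets)
  labs[labs == "unlabeled"] <- NA_character_
  if (nrow(timeline) > 0) {
    dur <- ep$triplet_dur %||% (ep$window[2] / 1000)
    k <- preswitch_exclusion_count(rt, dur)
    for (p in timeline$time_s) {
      labs[onsets >= p - k * dur & onsets < p] <- NA_character_
    }
    changes <- attr(timeline, "change_times")
    for (ch in changes) {
      resp <- timeline$time_s[timeline$time_s >= ch]
      if (length(resp) == 0) next
      labs[onsets >= ch & onsets <= resp[1]] <- NA_character_
    }
  } else {
    labs[] <- NA_character_
  }
  ep$labels <- labs
  ep
}

#' Select one pre-switch trial per button press
#'
#' For each press, selects the last triplet whose full epoch ends at or
#' before the press time -- the last complete triplet heard before the
#' subject reported the perceptual change -- and labels it with the percept
#' being switched *into*. Presses occurring before the first complete
#' triplet contribute no trial.
#'
#' @param ep A [labeled_epochs()] object (any window; selection is on the
#'   triplet grid).
#' @param timeline The button-press [percept_timeline()].
#' @return `ep` subset to the selected trials, labelled by incoming percept.
#' @export
select_preswitch_trials <- function(ep, timeline) {
  stopifnot(inherits(ep, "labeled_epochs"))
  if (nrow(timeline) < 1) {
    return(subset_epochs(ep, integer(0)))
  }
  dur <- ep$triplet_dur %||% (ep$window[2] / 1000)
  pick <- integer(0)
  labs <- character(0)
  for (i in seq_len(nrow(timeline))) {
    p <- timeline$time_s[i]
    k <- floor(p / dur - 1 + 1e-9) # triplet index (0-based) of last complete
    if (k < 0) next
    onset <- k * dur
    j <- which(abs(ep$trial_onsets - onset) < 1e-6)
    if (length(j) != 1) next
    pick <- c(pick, j)
    labs <- c(labs, timeline$percept[i])
  }
  out <- subset_epochs(ep, pick)
  out$labels <- labs
  out
}

# Subset a labeled_epochs object to given trial indices.
subset_epochs <- function(ep, idx) {
  ep$trials <- ep$trials[idx, , , drop = FALSE]
  ep$labels <- ep$labels[idx]
  ep$kept <- ep$kept[idx, , drop = FALSE]
  ep$trial_onsets <- ep$trial_onsets[idx]
  ep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the standard LFP preprocessing chain on a block
#'
#' Convenience wrapper: resample to 1 kHz, band-pass to the LFP range,
#' remove the 2.2-2.7 Hz narrow-band interference, epoch, reject artifacts
#' and label trials.
#'
#' @param block A [recording_block()] with stimulus and press timelines.
#' @param rt Subject mean reaction time (s).
#' @param window Epoch window `(pre, dur, post)` ms.
#' @param band LFP pass band (Hz).
#' @param n_discard Spatial components discarded by the narrow-band filter.
#' @param reject_sd Artifact rejection threshold (block SDs).
#' @return A labelled [labeled_epochs()] object.
#' @export
preprocess_lfp <- function(block, rt = 0, window = c(0, 600, 0),
                           band = c(1.5, 70), n_discard = 30,
                           reject_sd = 4) {
  stopifnot(inherits(block, "recording_block"))
  if (is.null(block$timeline)) stopf("Block carries no percept timeline.")
  block <- resample_to_1khz(block)
  block <- bandpass_lfp(block, band)
  block <- remove_narrowband_25(block, n_discard)
  ep <- epoch_triplets(block, window)
  ep <- reject_trials(ep, reject_sd)
  label_and_filter(ep, block$timeline, rt)
}
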