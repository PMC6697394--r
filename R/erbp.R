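# High-gamma (70-150 Hz) event-related band power: Hilbert-envelope
# log-power, normalized to the block mean and smoothed, feeding the same
# cluster-mass permutation machinery as the LFP analysis.

#' High-gamma band-power envelope of a recording block
#'
#' Per site: band-pass to the high-gamma range, take the squared magnitude
#' of the analytic signal (Hilbert transform) as the power envelope,
#' log-transform, normalize by subtracting the mean log-power over the whole
#' block, and smooth by a zero-phase 1.5-40 Hz band-pass. The log-domain
#' normalization makes the pipeline invariant to global amplitude scaling of
#' the recording.
#'
#' @param block A [recording_block()] at 1 kHz.
#' @param gamma_band High-gamma band (Hz).
#' @param smooth_band Smoothing band applied to the log-power trace (Hz).
#' @return A [recording_block()] whose `data` holds the normalized log-power
#'   envelope (attribute `measure = "erbp"`).
#' @export
highgamma_envelope <- function(block, gamma_band = c(70, 150),
                               smooth_band = c(1.5, 40)) {
  stopifnot(inherits(block, "recording_block"))
  for (s in seq_len(nrow(block$data))) {
    x <- butter_filtfilt(block$data[s, ], block$fs, gamma_band)
    pow <- pmax(Mod(analytic_signal(x))^2, .Machine$double.xmin)
    lp <- log(pow)
    lp <- lp - mean(lp)
    block$data[s, ] <- butter_filtfilt(lp, block$fs, smooth_band)
  }
  attr(block, "measure") <- "erbp"
  block
}

#' Cluster-mass permutation test on high-gamma band power
#'
#' Runs the ERBP analysis end to end on a continuous block: high-gamma
#' envelope extraction, triplet-locked epoching with the same windows and
#' labels as the LFP analysis, 4-SD artifact rejection applied to the ERBP
#' signal, and the identical cluster-level-mass permutation test with FDR
#' correction across sites.
#'
#' @param block A [recording_block()] with stimulus and press timelines.
#' @param rt Subject mean reaction time (s).
#' @param window Epoch window `(pre, dur, post)` ms.
#' @param n_perm,min_len,alpha,q,seed Passed to [aep_cluster_test()].
#' @param reject_sd Rejection threshold in block SDs of the ERBP signal.
#' @return A `site_stat_map` tibble, as from [aep_cluster_test()].
#' @export
erbp_cluster_test <- function(block, rt = 0, window = c(0, 600, 0),
                              n_perm = 10000, min_len = 20, alpha = 0.05,
                              q = 0.01, reject_sd = 4, seed = 1L) {
  stopifnot(inherits(block, "recording_block"))
  if (is.null(block$timeline)) stopf("Block carries no percept timeline.")
  env <- highgamma_envelope(resample_to_1khz(block))
  ep <- epoch_triplets(env, window)
  ep <- reject_trials(ep, reject_sd)
  ep <- label_and_filter(ep, block$timeline, rt)
  aep_cluster_test(ep,
    n_perm = n_perm, min_len = min_len,
    alpha = alpha, q = q, seed = seed
  )
}
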