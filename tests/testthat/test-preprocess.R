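make_tone_block <- function(freq, fs, dur = 10, n_sites = 1, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq * t)
  recording_block(
    matrix(rep(x, n_sites), nrow = n_sites, byrow = TRUE), fs,
    tibble::tibble(site = seq_len(n_sites), area = "HGPM")
  )
}

# RMS in the central half of a trace (edge effects excluded)
mid_rms <- function(x) {
  n <- length(x)
  sqrt(mean(x[round(n / 4):round(3 * n / 4)]^2))
}

test_that("resampling to 1 kHz preserves in-band tones and lengths", {
  b <- make_tone_block(10, fs = 2000, dur = 10)
  r <- resample_to_1khz(b)
  expect_equal(r$fs, 1000)
  t <- (seq_len(ncol(r$data)) - 1) / 1000
  ref <- sin(2 * pi * 10 * t)
  mid <- 2000:8000
  amp_ratio <- mid_rms(r$data[1, mid]) / mid_rms(ref[mid])
  expect_lt(abs(amp_ratio - 1), 0.01)
  # identity at 1 kHz
  b1 <- make_tone_block(10, fs = 1000)
  expect_identical(resample_to_1khz(b1)$data, b1$data)
  # non-integer acquisition rate: length follows floor(n * 1000 / fs) +- 1
  b2 <- make_tone_block(10, fs = 2034.5, dur = 7)
  n_in <- ncol(b2$data)
  n_out <- ncol(resample_to_1khz(b2)$data)
  expect_lte(abs(n_out - floor(n_in * 1000 / 2034.5)), 1)
  expect_error(resample_to_1khz(make_tone_block(1, fs = 500)), "fs")
})

test_that("the LFP band-pass has the specified frequency response", {
  drift <- bandpass_lfp(make_tone_block(0.1, 1000, dur = 40))
  expect_lt(
    mid_rms(drift$data[1, ]) / (1 / sqrt(2)), # input RMS of unit sine
    10^(-20 / 20)
  ) # >= 20 dB down
  inband <- bandpass_lfp(make_tone_block(30, 1000, dur = 20))
  gain <- mid_rms(inband$data[1, ]) / (1 / sqrt(2))
  expect_lt(abs(20 * log10(gain)), 1) # within 1 dB
  high <- bandpass_lfp(make_tone_block(200, 1000, dur = 20))
  expect_lt(mid_rms(high$data[1, ]) / (1 / sqrt(2)), 10^(-40 / 20))
})

band_power_25 <- function(x, fs) {
  sum(Mod(fft(x))[abs(bistream:::fft_freqs(length(x), fs)) >= 2.2 &
    abs(bistream:::fft_freqs(length(x), fs)) <= 2.7]^2)
}

test_that("shared 2.5 Hz interference is removed almost entirely", {
  withr::local_seed(5)
  fs <- 1000
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  common <- 10 * sin(2 * pi * 2.5 * t)
  data <- t(sapply(1:6, function(s) common * runif(1, 0.5, 1.5) + rnorm(length(t))))
  b <- recording_block(data, fs, tibble::tibble(site = 1:6, area = "STG"))
  out <- suppressWarnings(remove_narrowband_25(b, n_discard = 30))
  for (s in 1:6) {
    expect_lt(
      band_power_25(out$data[s, ], fs) / band_power_25(b$data[s, ], fs),
      0.01
    )
  }
})

test_that("signals without 2.2-2.7 Hz energy pass through unchanged", {
  fs <- 1000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 31.7 * t)
  b <- recording_block(rbind(x, 2 * x), fs,
                       tibble::tibble(site = 1:2, area = "PT"))
  out <- suppressWarnings(remove_narrowband_25(b, n_discard = 30))
  rel <- max(abs(out$data - b$data)) / max(abs(b$data))
  expect_lt(rel, 1e-3)
})

test_that("spatial component count is capped at n_sites - 1", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  data <- rbind(sin(2 * pi * 2.5 * t), cos(2 * pi * 2.5 * t))
  b <- recording_block(data, fs, tibble::tibble(site = 1:2, area = "PP"))
  expect_warning(remove_narrowband_25(b, n_discard = 30), "capped at 1")
  expect_error(
    remove_narrowband_25(
      recording_block(matrix(t, 1), fs, tibble::tibble(site = 1, area = "PP"))
    ),
    "at least 2"
  )
})

test_that("triplet epoching yields one trial per triplet and drops misfits", {
  sb <- mini_block(n_triplets = 50, n_sites = 2, seed = 21)
  ep <- epoch_triplets(sb$block)
  expect_equal(dim(ep$trials), c(50, 2, 600))
  expect_equal(ep$window, c(0, 600, 0))
  # 2-s embedding window: 2000 samples; edge triplets without full context drop
  ep2 <- epoch_triplets(sb$block, c(700, 600, 700))
  expect_equal(dim(ep2$trials)[3], 2000)
  expect_equal(dim(ep2$trials)[1], 50 - 4)
  expect_equal(ep2$trial_onsets[1], 1.2)
  # block with no stimulus timeline cannot be epoched
  nb <- recording_block(matrix(0, 1, 1000), 1000,
                        tibble::tibble(site = 1, area = "STG"))
  expect_error(epoch_triplets(nb), "timeline")
})

test_that("epoching with the bare triplet window is lossless", {
  sb <- mini_block(n_triplets = 20, n_sites = 2, seed = 22)
  ep <- epoch_triplets(sb$block)
  rebuilt <- do.call(cbind, lapply(seq_len(20), function(i) ep$trials[i, , ]))
  expect_equal(rebuilt, sb$block$data[, seq_len(20 * 600)])
})

test_that("4-SD rejection matches the Gaussian tail rate and is idempotent", {
  withr::local_seed(31)
  arr <- array(rnorm(500 * 1 * 600), dim = c(500, 1, 600))
  ep <- epochs_from_array(arr, rep(c("1-stream", "2-stream"), 250))
  ep <- reject_trials(ep)
  p_trial <- 1 - (1 - 2 * stats::pnorm(-4))^600
  n_rej <- sum(!ep$kept)
  expect_gte(n_rej, stats::qbinom(0.0025, 500, p_trial))
  expect_lte(n_rej, stats::qbinom(0.9975, 500, p_trial))
  # idempotent: block statistics always use all trials
  ep2 <- reject_trials(ep)
  expect_identical(ep$kept, ep2$kept)
  # an implanted 10-SD artifact spike is always masked
  arr[7, 1, 300] <- 10
  epx <- reject_trials(epochs_from_array(arr, ep$labels))
  expect_false(epx$kept[7, 1])
  # constant-voltage data (SD = 0) rejects nothing
  cst <- epochs_from_array(array(5, dim = c(10, 1, 50)),
                           rep(c("1-stream", "2-stream"), 5))
  expect_true(all(reject_trials(cst)$kept))
})

test_that("pre-press exclusion count reproduces the documented RT rule", {
  k <- bistream:::preswitch_exclusion_count
  expect_equal(k(0), 2L)
  expect_equal(k(0.36), 2L)
  expect_equal(k(0.6), 2L)
  expect_equal(k(0.65), 2L)
  expect_equal(k(0.78), 2L)
  expect_equal(k(1.24), 3L)
  expect_equal(k(1.29), 3L)
  expect_equal(k(1.34), 3L)
  expect_equal(k(1.48), 3L)
  expect_equal(k(2), 4L)
  expect_equal(k(3.22), 6L)
})

test_that("labelling excludes pre-first-press and pre-press epochs", {
  arr <- array(0, dim = c(20, 1, 600))
  ep <- epochs_from_array(arr, rep(NA_character_, 20)) # onsets 0, 0.6, ... 11.4
  tl <- percept_timeline(c(3.1, 7.3), c("2-stream", "1-stream"), 12)
  out <- label_and_filter(ep, tl, rt = 0)
  # before first press: unlabeled
  expect_true(all(is.na(out$labels[1:5]))) # onsets 0..2.4 < 3.1
  # k = 2 epochs before each press excluded: onsets in [press - 1.2, press)
  expect_true(is.na(out$labels[4])) # onset 1.8 in [1.9? no] -> check below
  excl1 <- which(ep$trial_onsets >= 3.1 - 1.2 & ep$trial_onsets < 3.1)
  excl2 <- which(ep$trial_onsets >= 7.3 - 1.2 & ep$trial_onsets < 7.3)
  expect_true(all(is.na(out$labels[excl1])))
  expect_true(all(is.na(out$labels[excl2])))
  # between-press and post-press trials carry the reported percept
  expect_equal(out$labels[8], "2-stream") # onset 4.2
  expect_equal(out$labels[14], "1-stream") # onset 7.8
  # labels never precede the first press
  expect_true(all(which(!is.na(out$labels)) > max(which(ep$trial_onsets < 3.1))))
})

test_that("slower reaction times widen the pre-press exclusion", {
  arr <- array(0, dim = c(30, 1, 600))
  ep <- epochs_from_array(arr, rep(NA_character_, 30))
  tl <- percept_timeline(c(4.0, 14.0), c("1-stream", "2-stream"), 18)
  k2 <- label_and_filter(ep, tl, rt = 0) # k = 2: onsets [12.8, 14) excluded
  k6 <- label_and_filter(ep, tl, rt = 3.22) # k = 6: onsets [10.4, 14)
  expect_equal(sum(is.na(k6$labels)) - sum(is.na(k2$labels)), 4)
  i108 <- which(abs(ep$trial_onsets - 10.8) < 1e-9)
  expect_true(is.na(k6$labels[i108]))
  expect_equal(k2$labels[i108], "1-stream")
})

test_that("control-block trials between change and response are excised", {
  arr <- array(0, dim = c(30, 1, 600))
  ep <- epochs_from_array(arr, rep(NA_character_, 30))
  tl <- percept_timeline(c(2, 10.9), c("1-stream", "2-stream"), 18,
    change_times = c(9.7)
  )
  out <- label_and_filter(ep, tl, rt = 0)
  mid <- which(ep$trial_onsets >= 9.7 & ep$trial_onsets <= 10.9)
  expect_true(all(is.na(out$labels[mid])))
  expect_equal(out$labels[which(ep$trial_onsets == 9.0)], "1-stream")
})

test_that("pre-switch selection picks the last complete triplet", {
  arr <- array(0, dim = c(30, 1, 600))
  ep <- epochs_from_array(arr, rep(NA_character_, 30))
  tl <- percept_timeline(c(10.0, 10.2 + 6), c("2-stream", "1-stream"), 18)
  out <- select_preswitch_trials(ep, tl)
  expect_equal(out$trial_onsets[1], 9.0) # triplet 9.0-9.6 complete at 10.0
  expect_equal(out$labels[1], "2-stream") # percept switched into
  tl2 <- percept_timeline(10.2, "1-stream", 18)
  out2 <- select_preswitch_trials(ep, tl2)
  expect_equal(out2$trial_onsets, 9.6) # 9.6-10.2 ends exactly at the press
  # zero presses -> empty selection; early press contributes nothing
  none <- select_preswitch_trials(
    ep, percept_timeline(numeric(0), character(0), 18)
  )
  expect_equal(dim(none$trials)[1], 0)
  early <- select_preswitch_trials(ep, percept_timeline(0.3, "1-stream", 18))
  expect_equal(dim(early$trials)[1], 0)
})
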