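#' Frequency of a tone a given number of semitones above a base tone
#'
#' The streaming stimulus uses pure tones A and B separated by `df` semitones
#' on the equal-tempered scale, so `f_A = f_B * 2^(df/12)`. Frequencies are
#' reported rounded to the nearest integer Hz (the convention used when such
#' stimuli are described); the unrounded value is used internally for
#' synthesis.
#'
#' @param f_b Base (B tone) frequency in Hz; must be positive.
#' @param df Semitone separation (may be fractional; typically 2, 6, 8, 12).
#' @param round_hz Round the result to the nearest integer Hz? Default `TRUE`.
#' @return Frequency of the A tone in Hz.
#' @examples
#' semitone_frequency(1000, 6) # 1414
#' semitone_frequency(1250, 8) # 1984
#' @export
semitone_frequency <- function(f_b, df, round_hz = TRUE) {
  if (any(!is.finite(f_b)) || any(f_b <= 0)) {
    stopf("`f_b` must be a positive, finite frequency in Hz.")
  }
  f <- f_b * 2^(df / 12)
  if (round_hz) round(f) else f
}

#' Construct an ABA_ triplet stimulus description
#'
#' A streaming block is a sequence of `n_triplets` ABA_ units: three tones
#' (A, B, A) of `tone_dur` seconds each, separated by `intra_gap` silences,
#' followed by an `inter_gap` silence. With the defaults each triplet lasts
#' 600 ms and a 500-triplet block lasts 300 s.
#'
#' @param f_b B-tone frequency (Hz).
#' @param df A-B separation in semitones.
#' @param n_triplets Number of triplet repeats in the block.
#' @param tone_dur,intra_gap,inter_gap Timing constants in seconds.
#' @return An object of class `triplet_stimulus`.
#' @export
triplet_stimulus <- function(f_b = 1000, df = 6, n_triplets = 500,
                             tone_dur = 0.1, intra_gap = 0.05,
                             inter_gap = 0.2) {
  if (n_triplets < 1) stopf("`n_triplets` must be at least 1.")
  if (any(c(tone_dur, intra_gap, inter_gap) <= 0)) {
    stopf("Timing constants must be positive.")
  }
  structure(
    list(
      f_b = f_b,
      df = df,
      f_a = semitone_frequency(f_b, df, round_hz = FALSE),
      tone_dur = tone_dur,
      intra_gap = intra_gap,
      inter_gap = inter_gap,
      triplet_dur = 3 * tone_dur + 2 * intra_gap + inter_gap,
      n_triplets = as.integer(n_triplets)
    ),
    class = "triplet_stimulus"
  )
}

#' @export
print.triplet_stimulus <- function(x, ...) {
  cat(sprintf(
    "ABA_ triplet stimulus: f_B = %g Hz, f_A = %g Hz (df = %g st)\n",
    x$f_b, semitone_frequency(x$f_b, x$df), x$df
  ))
  cat(sprintf(
    "  %d triplets of %g ms (total %g s)\n",
    x$n_triplets, 1000 * x$triplet_dur, x$n_triplets * x$triplet_dur
  ))
  invisible(x)
}

#' Tone-event table of a triplet stimulus
#'
#' Expands a [triplet_stimulus()] into its ordered tone events. Within each
#' triplet the A, B and second-A tones start at 0, 150 and 300 ms (with the
#' default timing constants), and triplet k starts at `k * triplet_dur`.
#'
#' @param stim A `triplet_stimulus`.
#' @return A tibble with one row per tone: `triplet` (1-based), `onset_s`,
#'   `duration_s`, `freq_hz`, `tone` (`"A"`, `"B"`, `"A2"`).
#' @export
build_triplet_sequence <- function(stim) {
  stopifnot(inherits(stim, "triplet_stimulus"))
  step <- stim$tone_dur + stim$intra_gap
  rel <- c(0, step, 2 * step)
  starts <- (seq_len(stim$n_triplets) - 1L) * stim$triplet_dur
  tibble::tibble(
    triplet = rep(seq_len(stim$n_triplets), each = 3L),
    onset_s = rep(starts, each = 3L) + rep(rel, stim$n_triplets),
    duration_s = stim$tone_dur,
    freq_hz = rep(c(stim$f_a, stim$f_b, stim$f_a), stim$n_triplets),
    tone = rep(c("A", "B", "A2"), stim$n_triplets)
  )
}

#' Construct a percept report timeline
#'
#' Records the subject's button presses: at each press time the subject
#' reports having switched into the given percept. Press times must be
#' strictly increasing and reported percepts must alternate.
#'
#' @param time_s Press times in seconds, strictly increasing.
#' @param percept Reported percept at each press: `"1-stream"` or
#'   `"2-stream"`, alternating.
#' @param block_dur Block duration in seconds.
#' @param change_times Optional stimulus-change times (control blocks in
#'   which percept alternation is driven by changes in the stimulus itself);
#'   used to excise trials between a change and the behavioural response.
#' @return A tibble of class `percept_timeline` with columns `time_s`,
#'   `percept` and attributes `block_dur` and `change_times`.
#' @export
percept_timeline <- function(time_s, percept, block_dur,
                             change_times = NULL) {
  stopifnot(length(time_s) == length(percept))
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    stopf("Press times must be strictly increasing.")
  }
  percept <- as.character(percept)
  bad <- setdiff(unique(percept), c("1-stream", "2-stream"))
  if (length(bad)) stopf("Unknown percept label: %s", bad[1])
  if (length(percept) > 1 && any(percept[-1] == percept[-length(percept)])) {
    stopf("Reported percepts must alternate between presses.")
  }
  out <- tibble::tibble(time_s = as.numeric(time_s), percept = percept)
  structure(out,
    block_dur = as.numeric(block_dur),
    change_times = change_times,
    class = c("percept_timeline", class(out))
  )
}

#' Percept reported at given times
#'
#' Returns the percept reported by the most recent button press at or before
#' each query time (boundary inclusive: at exactly a press time the newly
#' reported percept applies, since the press marks the onset of its report).
#' Times before the first press are `"unlabeled"`.
#'
#' @param timeline A [percept_timeline()].
#' @param t Query times (seconds), vectorized.
#' @return Character vector: `"1-stream"`, `"2-stream"` or `"unlabeled"`.
#' @export
percept_label_at <- function(timeline, t) {
  stopifnot(inherits(timeline, "percept_timeline"))
  if (nrow(timeline) == 0) return(rep("unlabeled", length(t)))
  idx <- findInterval(t, timeline$time_s)
  out <- rep("unlabeled", length(t))
  out[idx > 0] <- timeline$percept[idx[idx > 0]]
  out
}

#' Write / read stimulus and percept timelines as TSV event tables
#'
#' Event tables have columns `onset_s`, `duration_s`, `kind`, `value`.
#' Tone events carry `kind = "tone"` with the tone role and frequency in
#' `value`; presses carry `kind = "press"` with the reported percept;
#' stimulus changes (control blocks) carry `kind = "change"`.
#'
#' @param stim A `triplet_stimulus` or `NULL`.
#' @param timeline A `percept_timeline` or `NULL`.
#' @param path Output path.
#' @return `write_events_tsv()` returns `path` invisibly; `read_events_tsv()`
#'   returns a tibble of events.
#' @export
write_events_tsv <- function(path, stim = NULL, timeline = NULL) {
  rows <- list()
  if (!is.null(stim)) {
    seq_tbl <- build_triplet_sequence(stim)
    rows$tones <- tibble::tibble(
      onset_s = seq_tbl$onset_s, duration_s = seq_tbl$duration_s,
      kind = "tone", value = sprintf("%s:%g", seq_tbl$tone, seq_tbl$freq_hz)
    )
  }
  if (!is.null(timeline)) {
    rows$press <- tibble::tibble(
      onset_s = timeline$time_s, duration_s = 0,
      kind = "press", value = timeline$percept
    )
    ch <- attr(timeline, "change_times")
    if (!is.null(ch)) {
      rows$change <- tibble::tibble(
        onset_s = ch, duration_s = 0, kind = "change", value = ""
      )
    }
  }
  tbl <- dplyr::arrange(dplyr::bind_rows(rows), .data$onset_s)
  utils::write.table(tbl, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, fileEncoding = "UTF-8"
  ))
}
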