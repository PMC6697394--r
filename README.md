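# bistream

Percept-resolved analysis of multi-site intracranial recordings during
bistable auditory streaming.

## The problem

A repeating ABA_ tone-triplet sequence (tones A and B a few semitones
apart, one 600 ms triplet after another) is perceptually bistable:
listeners alternate spontaneously between hearing one integrated stream
and two segregated streams, and report each switch with a button press.
Because the sound is identical under both percepts, neural activity that
differs between percepts reflects perception itself. `bistream` is for
researchers analysing electrocorticographic (or other multi-channel
voltage) recordings from such experiments. It provides:

- **Stimulus and behaviour model** — triplet timelines
  (`f_A = f_B * 2^(df/12)`; 100/50/100/50/100/200 ms structure), percept
  report timelines, and dominance-duration statistics (gamma fits of
  normalized durations, rank-sum comparisons).
- **Preprocessing** — resampling to 1 kHz, zero-phase 1.5–70 Hz LFP
  band-pass, removal of 2.2–2.7 Hz interference by a spatial SVD filter
  plus temporal notch, triplet-locked epoching, per-channel 4-SD artifact
  rejection, percept labelling with reaction-time-aware exclusions.
- **Cluster-mass permutation statistics** — per site and time point, a
  two-sample t between percepts; temporally adjacent suprathreshold
  same-sign points (≥ 20 ms) form clusters scored by their mass
  `sum(t)`; the observed mass is compared with the permutation null of
  the most extreme mass (`p = (r+1)/(n+1)`), and site-level p values are
  FDR-corrected (Benjamini–Hochberg, q = 0.01) across sites.
- **Percept classification** — mean LFP in 12 × 50 ms bins per site,
  F-score ranking with recursive backward elimination, linear SVM,
  class balancing by undersampling, balanced test accuracy over 100
  random splits, and a feature-probability spatial map.
- **High-gamma ERBP** — 70–150 Hz Hilbert-envelope log-power, normalized
  to the block mean and smoothed, fed to the same cluster statistics.
- **Group-level embedding** — 2 s trials z-scored per site, pairwise
  affinities `a = exp(-λ·tan θ)` from folded cosine similarities,
  area-averaged kernels, one-dimensional diffusion-map coordinates from
  the first nontrivial eigenvector, and rank-sum tests for percept
  maintenance and pre-switch trials.
- **Synthetic-data generator** — recordings and behaviour with the
  statistical structure the analysis assumes (area-specific evoked
  components, a percept effect 60–130 ms after tone-B onset, 1/f noise,
  2.5 Hz interference, artifacts, gamma-distributed dominance
  durations), so the whole pipeline is testable without clinical data.

See `vignettes/bistream-methods.Rmd` for the model, its assumptions, and
every numerical choice.

## Worked example

```r
library(bistream)

cfg <- synthetic_config(n_sites = 8, effect_sites = c(1, 2, 5), seed = 1)
sb  <- simulate_lfp_block(cfg, triplet_stimulus(f_b = 1000, df = 6, n_triplets = 500))
ep  <- preprocess_lfp(sb$block, rt = 0.6)
ep
#> labeled_epochs: 500 trials x 8 sites x 600 samples (window 0+600+0 ms)
#>   labels: 1-stream=186, 2-stream=204, NA=110

map <- aep_cluster_test(ep, n_perm = 1000, seed = 1)
tibble::as_tibble(map)[, c(1:2, 5:8)]
#>    site area    p_site q_reject best_start_ms best_end_ms
#> 1     1 HGPM  0.000999 TRUE               223         271
#> 2     2 HGAL  0.000999 TRUE               223         273
#> 3     3 PT    1        FALSE               NA          NA
#> 4     4 PP    1        FALSE               NA          NA
#> 5     5 STG   0.000999 TRUE               223         266
#> 6     6 MTG   1        FALSE               NA          NA
#> 7     7 HGPM  1        FALSE               NA          NA
#> 8     8 HGAL  1        FALSE               NA          NA
glance(map)
#>   n_sites n_testable n_with_cluster n_fdr_rejected n_perm     q
#> 1       8          8              3              3   1000  0.01
```

The three sites that carry the injected percept effect (1, 2, 5) — and
only those — survive FDR, with their best clusters at 223–273 ms after
triplet onset, i.e. 73–123 ms after tone-B onset (tone B starts at
150 ms): the permutation test recovers both the sites and the latency of
the effect. `500` trials were cut, `110` were excluded (pre-first-press,
pre-press, or artifact-masked at all sites), and the rest labelled
1-stream/2-stream from the simulated button presses.

The same epochs feed the classifier (`bin_features()` then
`run_classification()`), the high-gamma path (`erbp_cluster_test()`), and
the embedding, e.g.:

```r
pb  <- remove_narrowband_25(bandpass_lfp(sb$block), 7)
ep2 <- label_and_filter(reject_trials(epoch_triplets(pb, c(700, 600, 700))),
                        sb$timeline, rt = 0.6)
emb <- build_embedding(ep2, lambda = 0.2)
maintenance_test(emb)
#>   subject    n1    n2        p    p_adj reject
#> 1 S1        136   149 3.18e-18 3.18e-18 TRUE
#> 2 pooled    136   149 3.18e-18 3.18e-18 TRUE
```

The 1-D embedding coordinates of the 2 s trials separate the two
percepts (two-sided rank-sum), without any label information entering
the embedding itself.

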