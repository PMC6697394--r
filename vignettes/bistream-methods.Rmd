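---
title: "Methods: percept-resolved analysis of intracranial recordings during auditory streaming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: percept-resolved analysis of intracranial recordings during auditory streaming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bistream)
```

## The problem

A sequence of ABA_ tone triplets — two pure tones A and B separated by a
few semitones, repeated every 600 ms — is perceptually bistable: listeners
spontaneously alternate between hearing one integrated "galloping" stream
and two segregated streams, and report each switch with a button press.
Because the stimulus is identical under both percepts, any neural activity
that differs between percepts reflects perception rather than acoustics.
`bistream` implements the statistical machinery for asking that question of
multi-site intracranial voltage recordings: which recording sites show
percept-dependent auditory evoked potentials (AEPs), can single 600 ms
trials be decoded, does high-gamma power carry the same information, and do
low-dimensional embeddings of auditory-cortex activity separate the
percepts at the group level?

The package ships a synthetic-data generator with the statistical structure
this analysis assumes, so every stage is testable end to end without any
clinical recording.

## Stimulus model

A triplet is three 100 ms tones (A, B, A) separated by 50 ms gaps and
followed by 200 ms of silence: 600 ms in total, giving a 300 ms onset
asynchrony between successive A tones and 600 ms between B tones. Tone A
sits `df` semitones above the base tone, `f_A = f_B * 2^(df/12)`; at
`f_B = 1000` Hz the conditions df = 2, 6, 8, 12 give 1122, 1414, 1587 and
2000 Hz. A 500-triplet block lasts 300 s. Frequencies are reported rounded
to integer Hz; synthesis uses the exact value.

Percept reports form a timeline of (press time, reported percept) pairs.
The label at time *t* is the percept of the most recent press at or before
*t*; the boundary is right-inclusive because the press marks the onset of
the new percept's report. Times before the first press are unlabeled.

## Preprocessing

Recordings (acquired at 2000–2034.5 Hz in the targeted setups) are
anti-alias filtered and resampled to 1 kHz, band-passed to the LFP range
(1.5–70 Hz, 4th-order Butterworth applied forward–backward so the filter is
zero-phase), and cleaned of narrow-band interference near 2.5 Hz — the
triplet rate is 1.67 Hz and slow interference at ~2.5 Hz destabilizes the
baseline. The 2.2–2.7 Hz component is removed in two steps: the
band-limited component of all sites is extracted by zero-phase FFT band
selection, the SVD of its unit-diagonal spatial correlation matrix is
taken, and the reconstruction of the first 30 spatial components (capped at
`n_sites - 1`) is subtracted from the broadband data; any residual energy
in the band is then notched per site. Only the narrow-band component is
ever subtracted, so broadband signal is untouched. We use FFT band
selection rather than an IIR band-stop because a Butterworth stop band of
relative width 5e-4 is numerically fragile under forward–backward
filtering, while the FFT projection is exact and zero-phase.

Epoching cuts one trial per triplet, time-locked to triplet onset: the
default (0, 600, 0) ms window for AEP/classification analyses, and a
(700, 600, 700) ms window — the triplet with its neighbours, 2 s in all —
for the embedding analysis. Trials whose window extends past the recording
are dropped. Artifact rejection is per acquisition channel: a trial is
masked at a site if any sample deviates from the within-block mean by more
than 4 within-block SDs. Block statistics always use all trials, which
makes rejection idempotent.

Trials are labelled with the percept reported at their onset. Excluded
from analysis: trials before the first press, and the *k* epochs
immediately preceding each press with `k = max(2, ceiling(rt / 0.6))`,
where `rt` is the subject's mean reaction time — the switch itself happened
roughly `rt` before the press, so those epochs have uncertain labels. The
rule reproduces the documented exclusion counts for reaction times from
0.36 to 3.22 s. In control blocks, where stimulus changes drive the
alternation, trials between a stimulus change and the behavioural response
to it are excised.

## Cluster-level-mass permutation statistics

At every site and time point a two-sample t statistic compares the trials
of the two percept classes. We use the pooled-variance t; the choice
between pooled and Welch is exposed but pooled is the default since class
variances are equal by construction in the null model and near-equal in
practice. Points with zero pooled variance are untestable and treated as
non-significant.

Suprathreshold points (uncorrected p < 0.05) are grouped into temporal
clusters of same-sign t values; clusters shorter than 20 samples (20 ms at
1 kHz) are discarded. Requiring a common sign follows standard
cluster-mass practice: an AEP deflection does not change sign within one
component. The cluster-level mass is the sum of member t values. The null
distribution of the most extreme cluster mass (maximum absolute value, 0
when no cluster forms) is built by randomly reassigning the class labels
over the retained trials of that site — class counts preserved, masks
respected — and recomputing the entire map per permutation. Observed
clusters get the Monte-Carlo p value `(r + 1) / (n + 1)`, which can never
be zero; members inherit the cluster p, all other points get p = 1, and a
site's summary p is the minimum over the epoch. Benjamini–Hochberg FDR at
q = 0.01 across sites controls the expected fraction of falsely selected
sites on the spatial map.

## Percept classification

Each labelled trial is summarized by the mean LFP in twelve 50 ms bins per
site. Each of 100 repetitions draws a random 4/5 training–1/5 test split,
z-scales every feature over the training and test sets separately, and
balances the training classes by undersampling the majority class (observed
imbalances reach 1:3; balancing the data, rather than reweighting, keeps
the SVM objective unchanged). Features are ranked by the F score — the
between-class squared deviations of the class means over the summed
within-class variances — and the top `D = ceiling(0.1 * training size)`
enter a recursive backward elimination: for `k = D ... 1`, a linear SVM
(`C = 1`) is trained on five random stratified 80/20 subtraining/validation
splits of the training set and the mean validation error recorded; the
final dimension `D*` is the smallest `k` attaining the minimum. The
held-out test set is scored with balanced accuracy (mean of per-class
recalls), which stays at 0.5 for degenerate majority-vote behaviour. The
per-feature probability of appearing in the selected set over repetitions
yields the classifier-driven spatial map; features above probability 0.3
are retained.

Two open choices deserve note. The z-scaling is per set (training and test
scaled by their own statistics), which is unusual relative to
train-derived scaling but is what the procedure we implement describes;
with ~50+ test trials the difference is negligible and the per-set variant
keeps the test set untouched by training statistics. The 80/20 proportion
of the internal validation split is our choice; the procedure we follow
fixes only the five repetitions.

## High-gamma event-related band power

The ERBP pipeline band-passes each site to 70–150 Hz, takes the squared
magnitude of the analytic signal (FFT-based Hilbert transform) as the
power envelope, log-transforms it, normalizes by subtracting the mean
log-power over the whole block, and smooths the trace with a zero-phase
1.5–40 Hz band-pass. Subtraction in the log domain (rather than division)
makes the pipeline exactly invariant to global amplitude scaling. The
resulting envelope is epoched, rejected (4-SD rule applied to the ERBP
signal) and labelled exactly like the LFP, and fed to the identical
cluster-mass permutation machinery.

## Group-level embedding

For each trial, the 2 s traces at auditory-cortex sites are z-scored over
their own time axis, removing per-trial amplitude and offset. Within each
area group — core (HGPM), superior-temporal-plane non-core (HGAL, PT, PP,
combined), and STG — the standardized traces of the group's sites are
concatenated per trial and pairwise cosine similarities computed with the
angle folded into [0°, 90°] (absolute cosine). Folding is the only reading
that keeps `tan` finite and single-signed: antiphase trials become
orthogonal-or-closer. The affinity is `a = exp(-lambda * tan(theta))`: 1
for collinear trials, 0 in the orthogonal limit (assigned exactly), and
strictly decreasing in between. `lambda` (0.2 default, 0.1 for
lower-variance subjects) sets the locality of the kernel. The subject's
kernel is the elementwise mean over the available area groups.

The one-dimensional embedding uses the first nontrivial eigenvector. We
row-normalize the affinity matrix to a Markov operator first: only the
normalized operator has the constant leading eigenvector that makes "first
nontrivial" well defined; the coordinates are the entries of the
second-largest-eigenvalue right eigenvector. The sign is fixed so the
largest-magnitude entry is positive, which makes repeated runs and
cross-subject pooling deterministic. A disconnected kernel is an error
(naming the components); an all-equal kernel is flagged uninformative.
Group statistics are two-sided Wilcoxon rank-sum tests on the embedded
coordinates — per subject and pooled after per-subject sign fixing — with
BH-FDR at 1% over the family. The pre-switch analysis embeds one trial per
press (the last complete triplet before it, labelled by the percept
switched into) and pools switches across subjects.

## Dominance-duration statistics

The duration of the percept reported at press *k* is the time to press
*k + 1*; the first reported percept of a block and the final truncated
interval are dropped (the final interval has no closing press, so its
duration is censored — we drop it rather than model censoring). Durations
are normalized to unit mean per group, fitted by maximum-likelihood gamma
(method-of-moments available as a fallback), and compared between
conditions by two-sided rank-sum tests, exact for small tie-free samples
and normally approximated with tie correction otherwise.

## The synthetic generator

`synthetic_config()` encodes the study conditions the pipeline targets:
1 kHz sampling, 500-triplet (300 s) blocks, dominance durations from gamma
distributions with shape 2 and means of 22.9 s (1-stream) and 32.6 s
(2-stream), button presses delayed by a truncated-normal reaction time
(mean 0.6 s by default), and a percept effect expressed 60–130 ms after
tone-B onset. Every tone adds an area-specific Gabor-like evoked component:
short-latency (~30 ms), narrow, large in core auditory cortex (HGPM),
progressively later and broader in HGAL/PT/PP and STG/MTG, small and late
at non-auditory sites. The percept effect is an additive raised-cosine
component after tone B, split ±effect/2 between the percepts so the AEP
difference peaks at `effect_amp` (default 10 µV; observed AEP differences
span roughly 4–18 µV). The background is 1/f (spectrally shaped white)
noise plus white noise at a configurable total SD (20 µV default), a 2.5 Hz
sinusoid shared across sites with per-site gain (the interference the
spatial filter exists for), and Poisson-placed 50 ms bipolar artifacts at
8–12 times the noise SD — large enough to trip the 4-SD rejection rule by
construction. An optional 100 Hz burst after tone B, with or without a
percept-dependent amplitude, exercises the ERBP path in both the positive
and the negative direction.

All randomness flows through a single seed: identical seeds give
bit-identical blocks. The generator emulates the *statistical* structure
the analysis assumes — it makes no claim to biophysical fidelity, volume
conduction, electrode geometry, non-stationarity of real recordings, or
epileptiform activity. Passing tests therefore demonstrate that the
statistics behave as specified under their own model assumptions, not that
real recordings satisfy those assumptions.

## Numerical choices and test scales

Filters are 4th-order Butterworth run forward–backward; the narrow-band
notch is an FFT projection; the Hilbert transform is the standard FFT
construction; eigen-decomposition is done on the symmetrized
`D^(-1/2) A D^(-1/2)` operator for stability. Monte-Carlo p values use the
`(r + 1)/(n + 1)` estimator and the permutation engine recomputes all
pointwise t values per permutation via class-sum identities (one matrix
product per chunk of permutations).

The test suite exercises the permutation test at 50 sites x 500 triplets x
1000 permutations over 20 seeded replicates for null calibration, one
10-effect-site block for power, classifier runs at 10 sites x 100
repetitions, and embeddings of up to 400 trials; these sizes give stable
pass/fail behaviour for the property-based checks while keeping a full run
of the suite in the tens of minutes on a single core. The acceptance
script uses the same generator settings at moderately reduced replicate
counts and records every quantity with the problem size it was computed at.

## Known limitations

The demodulated-band-transform denoising used in some acquisition chains
is not reimplemented; standard zero-phase filtering stands in its place, as
the downstream statistics are the contribution of interest. Cluster
formation is purely temporal (per site) by design; no spatiotemporal
clustering is attempted. The embedding is strictly one-dimensional with no
out-of-sample extension. The rank-sum tests treat trials as exchangeable
within a block; temporal autocorrelation between neighbouring trials is
ignored, exactly as in the procedure implemented.
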