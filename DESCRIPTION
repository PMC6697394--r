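Package: bistream
Title: Analysis of Intracranial Recordings During Bistable Auditory Streaming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-site intracranial voltage recordings
    acquired while listeners report bistable percepts of ABA_ tone-triplet
    streaming sequences. Provides triplet-locked epoching and percept
    labelling, cluster-level-mass permutation statistics on auditory evoked
    potentials with false-discovery-rate control across recording sites,
    percept classification by recursive F-score feature selection with a
    support vector machine, high-gamma (70-150 Hz) Hilbert-envelope band-power
    analysis, one-dimensional diffusion-map embeddings of trials with
    rank-sum group statistics, and gamma-distribution modelling of percept
    dominance durations. A synthetic-data generator emulates the statistical
    structure of such recordings and behaviour so the full pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    e1071,
    fitdistrplus,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
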