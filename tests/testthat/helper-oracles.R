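# Independent oracles used by both the unit and the acceptance suites.

# Clusters by explicit scan over a significance vector (oracle for
# form_clusters and for exhaustive permutation enumeration).
brute_clusters <- function(tvec, pvec, min_len, alpha = 0.05) {
  sig <- !is.na(tvec) & !is.na(pvec) & pvec < alpha
  out <- list()
  i <- 1
  n <- length(tvec)
  while (i <= n) {
    if (!sig[i]) {
      i <- i + 1
      next
    }
    j <- i
    while (j < n && sig[j + 1] && sign(tvec[j + 1]) == sign(tvec[i])) j <- j + 1
    if (j - i + 1 >= min_len) {
      out[[length(out) + 1]] <- c(start = i, end = j, mass = sum(tvec[i:j]))
    }
    i <- j + 1
  }
  out
}

# Epochs whose two percept classes follow different deterministic
# temporal templates plus white noise; used for embedding tests.
two_template_epochs <- function(n_per_class = 60, n_sites = 5, n_time = 400,
                                snr = 1, seed = 1) {
  withr::with_seed(seed, {
    t1 <- sin(2 * pi * 3 * seq_len(n_time) / n_time)
    t2 <- sin(2 * pi * 5 * seq_len(n_time) / n_time)
    n <- 2 * n_per_class
    arr <- array(rnorm(n * n_sites * n_time, sd = 1 / snr),
                 dim = c(n, n_sites, n_time))
    labels <- rep(c("1-stream", "2-stream"), each = n_per_class)
    for (i in seq_len(n)) {
      tpl <- if (labels[i] == "1-stream") t1 else t2
      for (s in seq_len(n_sites)) arr[i, s, ] <- arr[i, s, ] + tpl
    }
    epochs_from_array(arr, labels,
      areas = c("HGPM", "HGAL", "PT", "PP", "STG")[seq_len(n_sites)]
    )
  })
}
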