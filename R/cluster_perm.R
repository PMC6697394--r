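# Site-wise cluster-level-mass permutation test on evoked-potential
# differences between percept classes, with BH-FDR across recording sites.

# Map percept labels to classes 1/2; NA for excluded trials.
percept_class <- function(labels) {
  cls <- rep(NA_integer_, length(labels))
  cls[labels == "1-stream"] <- 1L
  cls[labels == "2-stream"] <- 2L
  cls
}

# Pooled-variance two-sample t statistics for many label assignments at
# once. X: trials x time; assign: n_perm x n1 matrix of class-1 row indices.
# Returns an n_perm x time matrix of t values (NA where the pooled variance
# vanishes). Uses the identity
# (n1-1) v1 + (n2-1) v2 = sum(x^2) - n1 m1^2 - n2 m2^2,
# so only class-1 sums are needed per permutation.
t_matrix_perms <- function(x, assign, n1, n2) {
  s_all <- colSums(x)
  ss_all <- colSums(x * x)
  n_perm <- nrow(assign)
  n <- n1 + n2
  ind <- matrix(0, n_perm, nrow(x))
  ind[cbind(rep(seq_len(n_perm), times = ncol(assign)), as.vector(assign))] <- 1
  m1 <- (ind %*% x) / n1
  m2 <- sweep(-n1 * m1, 2, s_all, `+`) / n2
  sp2 <- sweep(-(n1 * m1^2 + n2 * m2^2), 2, ss_all, `+`) / (n - 2)
  tmat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tmat[!is.finite(tmat) | sp2 <= 0] <- NA_real_
  tmat
}

#' Pointwise two-sample t statistics between percept classes
#'
#' Computes, for every site and time point, the averaged evoked potentials of
#' the two percept classes over retained labelled trials, the pooled-variance
#' two-sample t statistic, and its two-tailed p value. Sites where either
#' class has fewer than 2 retained trials are flagged untestable (all-`NA`
#' rows). Time points with zero pooled variance are returned as `NA` and are
#' treated as non-significant downstream.
#'
#' @param ep A labelled [labeled_epochs()] object.
#' @return A list of class `pointwise_stats`: `aep1`, `aep2`, `tmat`, `praw`
#'   (site x time matrices), `n1`, `n2` (per-site class counts), `testable`.
#' @export
pointwise_t <- function(ep) {
  stopifnot(inherits(ep, "labeled_epochs"))
  d <- dim(ep$trials)
  cls <- percept_class(ep$labels)
  aep1 <- aep2 <- tmat <- praw <- matrix(NA_real_, d[2], d[3])
  n1s <- n2s <- integer(d[2])
  for (s in seq_len(d[2])) {
    use <- !is.na(cls) & ep$kept[, s]
    c1 <- which(use & cls == 1L)
    c2 <- which(use & cls == 2L)
    n1s[s] <- length(c1)
    n2s[s] <- length(c2)
    if (length(c1) >= 1) aep1[s, ] <- colMeans(ep$trials[c1, s, , drop = FALSE])
    if (length(c2) >= 1) aep2[s, ] <- colMeans(ep$trials[c2, s, , drop = FALSE])
    if (length(c1) < 2 || length(c2) < 2) next
    x <- ep$trials[c(c1, c2), s, ]
    tv <- t_matrix_perms(
      x, matrix(seq_along(c1), nrow = 1),
      length(c1), length(c2)
    )[1, ]
    df <- length(c1) + length(c2) - 2
    tmat[s, ] <- tv
    praw[s, ] <- 2 * pt(-abs(tv), df)
  }
  structure(
    list(
      aep1 = aep1, aep2 = aep2, tmat = tmat, praw = praw,
      n1 = n1s, n2 = n2s, testable = n1s >= 2 & n2s >= 2
    ),
    class = "pointwise_stats"
  )
}

#' Group suprathreshold t scores into temporal clusters
#'
#' Forms maximal runs of temporally adjacent time points whose uncorrected
#' p value is below `alpha` and whose t statistics share a sign; runs
#' spanning fewer than `min_len` samples (20 samples = 20 ms at 1 kHz) are
#' discarded. `NA` t values (untestable points) break runs.
#'
#' @param tvec Numeric vector of t statistics over time at one site.
#' @param pvec Matching uncorrected two-tailed p values.
#' @param min_len Minimum cluster extent in samples.
#' @param alpha Pointwise threshold.
#' @return A tibble with one row per cluster: `start`, `end` (1-based sample
#'   indices, inclusive), `sign`, `mass` (sum of member t values).
#' @export
form_clusters <- function(tvec, pvec, min_len = 20, alpha = 0.05) {
  stopifnot(min_len >= 1, length(tvec) == length(pvec))
  code <- integer(length(tvec))
  sig <- !is.na(tvec) & !is.na(pvec) & pvec < alpha
  code[sig] <- sign(tvec[sig])
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0 & r$lengths >= min_len
  tibble::tibble(
    start = starts[keep],
    end = ends[keep],
    sign = r$values[keep],
    mass = vapply(
      which(keep),
      function(i) sum(tvec[starts[i]:ends[i]]),
      numeric(1)
    )
  )
}

#' Cluster-level mass of a cluster
#'
#' The sum of the member t statistics over all time points in the cluster.
#'
#' @param tvec t statistics over time.
#' @param start,end Inclusive sample-index range of the cluster.
#' @return The cluster-level mass t score.
#' @export
cluster_mass <- function(tvec, start, end) {
  stopifnot(start >= 1, end >= start, end <= length(tvec))
  sum(tvec[start:end])
}

# Maximum-|mass| cluster statistic of one t vector; 0 when no cluster forms.
max_cluster_stat <- function(tvec, df, min_len, alpha) {
  tcrit <- qt(1 - alpha / 2, df)
  code <- integer(length(tvec))
  sig <- !is.na(tvec) & abs(tvec) > tcrit
  code[sig] <- sign(tvec[sig])
  r <- rle(code)
  keep <- r$values != 0 & r$lengths >= min_len
  if (!any(keep)) return(0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  masses <- vapply(
    which(keep),
    function(i) sum(tvec[starts[i]:ends[i]]),
    numeric(1)
  )
  masses[which.max(abs(masses))]
}

#' Permutation null distribution of the maximum cluster-level mass
#'
#' Randomly reassigns percept labels 1 and 2 to the retained trials at one
#' site (preserving the class counts), recomputes the full pointwise t map,
#' thresholds, clusters and takes the most extreme (maximum |mass|)
#' cluster-level mass per permutation; permutations in which no cluster
#' survives contribute 0.
#'
#' @param ep A labelled [labeled_epochs()] object.
#' @param site Site index.
#' @param n_perm Number of permutations.
#' @param min_len,alpha Clustering parameters, as in [form_clusters()].
#' @param seed Integer seed (reproducible null under a fixed seed).
#' @return Numeric vector of `n_perm` null `t_cls` values.
#' @export
permutation_null <- function(ep, site, n_perm = 10000, min_len = 20,
                             alpha = 0.05, seed = 1L) {
  stopifnot(inherits(ep, "labeled_epochs"), n_perm >= 1)
  cls <- percept_class(ep$labels)
  use <- which(!is.na(cls) & ep$kept[, site])
  n1 <- sum(cls[use] == 1L)
  n2 <- sum(cls[use] == 2L)
  if (n1 < 2 || n2 < 2) stopf("Site %d is untestable (n1=%d, n2=%d).",
                              site, n1, n2)
  x <- ep$trials[use, site, ]
  n <- n1 + n2
  with_seed(seed, {
    out <- numeric(n_perm)
    chunk <- 2000L
    done <- 0L
    while (done < n_perm) {
      m <- min(chunk, n_perm - done)
      assign <- t(vapply(
        seq_len(m), function(i) sample.int(n, n1),
        integer(n1)
      ))
      tmat <- t_matrix_perms(x, assign, n1, n2)
      out[done + seq_len(m)] <- apply(
        tmat, 1, max_cluster_stat,
        df = n - 2, min_len = min_len, alpha = alpha
      )
      done <- done + m
    }
    out
  })
}

#' Monte-Carlo p value of an observed cluster mass
#'
#' `p = (r + 1) / (n + 1)` where `r` counts null values at least as extreme
#' (in absolute value) as the observed statistic, out of `n` permutations.
#' Never returns 0.
#'
#' @param t_obs Observed cluster-level mass.
#' @param null Null distribution from [permutation_null()].
#' @return Monte-Carlo p value in `[1/(n+1), 1]`.
#' @export
monte_carlo_p <- function(t_obs, null) {
  r <- sum(abs(null) >= abs(t_obs))
  (r + 1) / (length(null) + 1)
}

#' Spread cluster p values over their member time points
#'
#' Each cluster's Monte-Carlo p value is assigned to every time point it
#' spans; all points outside any cluster get an adjusted p of 1.
#'
#' @param clusters Cluster tibble ([form_clusters()]) with a `p` column.
#' @param n_time Number of time points.
#' @return Numeric vector of adjusted pointwise p values.
#' @export
assign_adjusted_p <- function(clusters, n_time) {
  p <- rep(1, n_time)
  for (i in seq_len(nrow(clusters))) {
    p[clusters$start[i]:clusters$end[i]] <- clusters$p[i]
  }
  p
}

#' Benjamini-Hochberg selection of significant sites
#'
#' Step-up FDR control at level `q` applied to the per-site p values.
#'
#' @param p_site Per-site p values (NA allowed for untestable sites).
#' @param q FDR level.
#' @return Logical vector: site rejected (significant) or not.
#' @export
fdr_across_sites <- function(p_site, q = 0.01) {
  stopifnot(q > 0, q < 1)
  adj <- p.adjust(p_site, method = "BH")
  !is.na(adj) & adj <= q
}

#' Cluster-mass permutation test of AEP percept differences, all sites
#'
#' Runs the full site-wise analysis: pointwise pooled-variance t statistics
#' between percept classes, temporal clustering of suprathreshold points,
#' Monte-Carlo cluster p values against the per-site maximum-cluster-mass
#' permutation null, the per-site summary p (minimum adjusted pointwise p
#' over the epoch), and BH-FDR across sites.
#'
#' @param ep A labelled [labeled_epochs()] object.
#' @param n_perm Permutations per site.
#' @param min_len Minimum cluster extent (samples).
#' @param alpha Pointwise and cluster significance threshold.
#' @param q FDR level across sites.
#' @param seed Integer seed.
#' @return A tibble of class `site_stat_map`: one row per site with columns
#'   `site`, `area`, `n1`, `n2`, `p_site`, `q_reject`, `best_start_ms`,
#'   `best_end_ms`, `best_sign`, `best_mass`, `n_clusters`. Per-site cluster
#'   tables (with Monte-Carlo p values) are in `attr(, "clusters")`; the
#'   pointwise statistics in `attr(, "pointwise")`.
#' @export
aep_cluster_test <- function(ep, n_perm = 10000, min_len = 20, alpha = 0.05,
                             q = 0.01, seed = 1L) {
  stopifnot(inherits(ep, "labeled_epochs"))
  pw <- pointwise_t(ep)
  n_sites <- dim(ep$trials)[2]
  n_time <- dim(ep$trials)[3]
  site_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_sites))
  cluster_list <- vector("list", n_sites)
  p_site <- rep(NA_real_, n_sites)
  best <- matrix(NA_real_, n_sites, 4) # start, end, sign, mass
  n_cl <- integer(n_sites)
  for (s in seq_len(n_sites)) {
    if (!pw$testable[s]) next
    cl <- form_clusters(pw$tmat[s, ], pw$praw[s, ], min_len, alpha)
    if (nrow(cl) == 0) {
      p_site[s] <- 1
      cluster_list[[s]] <- cbind(cl, p = numeric(0))
      next
    }
    null <- permutation_null(ep, s, n_perm, min_len, alpha,
      seed = site_seeds[s]
    )
    cl$p <- vapply(cl$mass, monte_carlo_p, numeric(1), null = null)
    cluster_list[[s]] <- cl
    padj <- assign_adjusted_p(cl, n_time)
    p_site[s] <- min(padj)
    n_cl[s] <- nrow(cl)
    # best cluster: smallest p, ties broken by the larger |mass| (many
    # clusters can sit at the Monte-Carlo floor 1/(n+1))
    cand <- which(cl$p == min(cl$p))
    b <- cand[which.max(abs(cl$mass[cand]))]
    best[s, ] <- c(cl$start[b], cl$end[b], cl$sign[b], cl$mass[b])
  }
  ms0 <- -ep$window[1] # time of sample 1 relative to triplet onset, ms
  out <- tibble::tibble(
    site = ep$sites$site, area = ep$sites$area,
    n1 = pw$n1, n2 = pw$n2,
    p_site = p_site,
    q_reject = fdr_across_sites(p_site, q),
    best_start_ms = (best[, 1] - 1) / ep$fs * 1000 + ms0,
    best_end_ms = best[, 2] / ep$fs * 1000 + ms0,
    best_sign = best[, 3],
    best_mass = best[, 4],
    n_clusters = n_cl
  )
  structure(out,
    clusters = cluster_list, pointwise = pw,
    n_perm = n_perm, q = q, alpha = alpha, min_len = min_len,
    class = c("site_stat_map", class(out))
  )
}
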