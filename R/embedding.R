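# One-dimensional diffusion-map embedding of 2-s trials from auditory
# cortex, and rank-sum group statistics on the embedded coordinates for
# percept maintenance and for pre-switch trials.

#' Standardize single-trial traces over their own time axis
#'
#' Each (trial, site) trace is z-scored over its time samples, removing
#' per-trial amplitude and offset differences before affinities are
#' computed. Traces with zero SD cannot be standardized; those site-trials
#' are masked out (with a warning).
#'
#' @param ep A [labeled_epochs()] object (typically the 2-s embedding
#'   window `(700, 600, 700)` ms).
#' @return `ep` with standardized `trials` and an updated `kept` mask.
#' @export
zscore_trials <- function(ep) {
  stopifnot(inherits(ep, "labeled_epochs"))
  d <- dim(ep$trials)
  n_dropped <- 0L
  for (s in seq_len(d[2])) {
    x <- ep$trials[, s, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = d[1])
    mu <- rowMeans(x)
    sdv <- apply(x, 1, sd)
    bad <- sdv == 0
    sdv[bad] <- 1
    ep$trials[, s, ] <- (x - mu) / sdv
    if (any(bad)) {
      ep$kept[bad, s] <- FALSE
      n_dropped <- n_dropped + sum(bad)
    }
  }
  if (n_dropped > 0) {
    warnf("%d constant site-trial traces could not be standardized; masked.",
          n_dropped)
  }
  ep
}

#' Affinity kernel from pairwise trial angles
#'
#' For each pair of trials, the cosine similarity of their concatenated
#' standardized traces is computed with the angle restricted to [0, 90]
#' degrees (absolute cosine, folding antiphase pairs onto orthogonal-or-
#' closer), then mapped through `a = exp(-lambda * tan(theta))`. Collinear
#' trials get affinity 1, orthogonal trials affinity 0, everything else a
#' subunitary value; the exponential map enhances locality in trial space.
#'
#' @param z Trial x feature matrix (concatenated standardized traces over
#'   the sites of one area group).
#' @param lambda Positive scaling factor of the kernel.
#' @return Symmetric trial x trial affinity matrix with unit diagonal.
#' @export
cosine_affinity <- function(z, lambda = 0.2) {
  stopifnot(lambda > 0)
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0)) stopf("Zero-norm trial trace; standardize first.")
  cosx <- abs(tcrossprod(z / nrm))
  cosx[cosx > 1] <- 1
  theta <- acos(cosx)
  a <- exp(-lambda * tan(theta))
  a[cosx == 0] <- 0 # theta = 90 degrees maps to the limit value exactly
  diag(a) <- 1
  (a + t(a)) / 2
}

#' Mean affinity kernel over area groups
#'
#' Elementwise mean of the per-area affinity kernels (core auditory cortex
#' HGPM; superior-temporal-plane non-core HGAL/PT/PP combined; STG). Groups
#' without recording sites are skipped with a warning; at least one group
#' must be available.
#'
#' @param kernels Named list of affinity matrices (NULL entries allowed).
#' @return The mean affinity matrix.
#' @export
mean_area_kernel <- function(kernels) {
  kernels <- kernels[!vapply(kernels, is.null, logical(1))]
  if (length(kernels) == 0) stopf("No auditory-area kernel available.")
  dims <- vapply(kernels, dim, integer(2))
  if (any(dims != dims[, 1])) stopf("Kernels have mismatched dimensions.")
  Reduce(`+`, kernels) / length(kernels)
}

# Connected components of the affinity graph (edges where a > tol).
kernel_components <- function(a, tol = 1e-12) {
  n <- nrow(a)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(a[v, ] > tol & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' One-dimensional diffusion-map embedding of an affinity kernel
#'
#' Row-normalizes the affinity matrix to a Markov transition operator, whose
#' leading eigenvector is constant (trivial); the trial coordinates are the
#' entries of the eigenvector with the second-largest eigenvalue -- the
#' first nontrivial one. The sign is fixed so the largest-magnitude entry is
#' positive, giving deterministic output across repetitions and subjects.
#'
#' @param a Symmetric nonnegative affinity matrix ([cosine_affinity()] /
#'   [mean_area_kernel()]).
#' @return List of class `trial_embedding_basis`: `coord` (per-trial
#'   coordinate), `eigenvalue` (the first nontrivial eigenvalue),
#'   `uninformative` (TRUE when the kernel carries no structure).
#' @export
embed_1d <- function(a) {
  stopifnot(nrow(a) == ncol(a))
  if (any(a < 0)) stopf("Affinity matrix must be nonnegative.")
  if (max(abs(a - t(a))) > 1e-8) stopf("Affinity matrix must be symmetric.")
  comp <- kernel_components(a)
  if (max(comp) > 1) {
    sizes <- table(comp)
    stopf(
      "Affinity kernel is disconnected (%d components of sizes %s).",
      max(comp), paste(sizes, collapse = ", ")
    )
  }
  deg <- rowSums(a)
  dhalf <- 1 / sqrt(deg)
  m <- a * tcrossprod(dhalf) # D^{-1/2} A D^{-1/2}, symmetric
  dec <- eigen(m, symmetric = TRUE)
  # right eigenvector of the Markov operator D^{-1} A
  coord <- dhalf * dec$vectors[, 2]
  lam2 <- dec$values[2]
  uninformative <- abs(lam2) < 1e-10 ||
    abs(lam2 - dec$values[min(3, length(dec$values))]) < 1e-12
  if (uninformative) {
    warnf("Second eigenvalue degenerate or ~0; embedding uninformative.")
  }
  i <- which.max(abs(coord))
  if (coord[i] < 0) coord <- -coord
  structure(
    list(coord = coord, eigenvalue = lam2, uninformative = uninformative),
    class = "trial_embedding_basis"
  )
}

# Default auditory area grouping for the mean kernel.
default_area_groups <- function() {
  list(
    HGPM = "HGPM",
    STP = c("HGAL", "PT", "PP"),
    STG = "STG"
  )
}

#' Embed the trials of an epochs object on one dimension
#'
#' Full embedding pipeline for one subject and block: standardize traces,
#' build one affinity kernel per auditory area group (concatenating the
#' standardized traces of the group's sites), average the kernels, and take
#' the first nontrivial eigenvector of the row-normalized operator as the
#' trial coordinate. Only trials retained at all sites of the used groups
#' enter the embedding; no percept information is used until the coordinates
#' are labelled afterwards.
#'
#' @param ep A [labeled_epochs()] object (2-s windows recommended).
#' @param lambda Kernel scaling factor (0.2 or 0.1 in practice).
#' @param area_groups Named list of area-label groups; defaults to HGPM,
#'   \{HGAL, PT, PP\}, STG.
#' @param subject Optional subject id stored alongside coordinates.
#' @return A tibble of class `trial_embedding`: `subject`, `trial`,
#'   `onset_s`, `coord`, `label` (percept or `NA`).
#' @export
build_embedding <- function(ep, lambda = 0.2,
                            area_groups = default_area_groups(),
                            subject = NA_character_) {
  stopifnot(inherits(ep, "labeled_epochs"))
  ep <- zscore_trials(ep)
  groups <- lapply(area_groups, function(gr) which(ep$sites$area %in% gr))
  avail <- vapply(groups, length, integer(1)) > 0
  if (!any(avail)) stopf("No sites in any auditory area group.")
  if (!all(avail)) {
    warnf("Area group(s) %s have no sites; mean over the remaining.",
          paste(names(groups)[!avail], collapse = ", "))
  }
  use_sites <- unlist(groups[avail])
  keep <- which(apply(ep$kept[, use_sites, drop = FALSE], 1, all))
  if (length(keep) < 3) stopf("Fewer than 3 trials retained for embedding.")
  kernels <- lapply(groups[avail], function(sites) {
    z <- do.call(cbind, lapply(sites, function(s) ep$trials[keep, s, ]))
    cosine_affinity(z, lambda)
  })
  basis <- embed_1d(mean_area_kernel(kernels))
  out <- tibble::tibble(
    subject = subject,
    trial = keep,
    onset_s = ep$trial_onsets[keep],
    coord = basis$coord,
    label = ep$labels[keep]
  )
  structure(out,
    eigenvalue = basis$eigenvalue, lambda = lambda,
    class = c("trial_embedding", class(out))
  )
}

# Rank-sum p value between the two percept classes of one coordinate set.
ranksum_embedding <- function(coord, label) {
  g1 <- coord[label == "1-stream"]
  g2 <- coord[label == "2-stream"]
  if (length(g1) == 0 || length(g2) == 0) return(NA_real_)
  ranksum_p(g1, g2)
}

#' Percept-maintenance test on embedded coordinates
#'
#' Two-sided Wilcoxon rank-sum tests of 1-stream versus 2-stream embedded
#' coordinates, per subject and pooled over subjects (coordinates
#' concatenated after each subject's deterministic sign fixing), with BH-FDR
#' correction at `q` over the family of tests.
#'
#' @param embeddings A `trial_embedding` tibble or (named) list of them, one
#'   per subject.
#' @param q FDR level for the correction over the family.
#' @return A tibble: `subject` (`"pooled"` for the combined test), `n1`,
#'   `n2`, `p`, `p_adj`, `reject`. Subjects missing a class are untestable
#'   (`NA` p).
#' @export
maintenance_test <- function(embeddings, q = 0.01) {
  if (inherits(embeddings, "trial_embedding")) {
    embeddings <- list(embeddings)
  }
  if (is.null(names(embeddings)) || any(names(embeddings) == "")) {
    names(embeddings) <- vapply(seq_along(embeddings), function(i) {
      s <- embeddings[[i]]$subject[1]
      if (is.na(s)) paste0("S", i) else s
    }, character(1))
  }
  rows <- purrr::map2(embeddings, names(embeddings), function(emb, nm) {
    lab <- emb$label
    ok <- !is.na(lab)
    tibble::tibble(
      subject = nm,
      n1 = sum(lab[ok] == "1-stream"),
      n2 = sum(lab[ok] == "2-stream"),
      p = ranksum_embedding(emb$coord[ok], lab[ok])
    )
  })
  pooled_coord <- unlist(lapply(embeddings, function(e) e$coord))
  pooled_lab <- unlist(lapply(embeddings, function(e) e$label))
  ok <- !is.na(pooled_lab)
  rows$pooled <- tibble::tibble(
    subject = "pooled",
    n1 = sum(pooled_lab[ok] == "1-stream"),
    n2 = sum(pooled_lab[ok] == "2-stream"),
    p = ranksum_embedding(pooled_coord[ok], pooled_lab[ok])
  )
  out <- dplyr::bind_rows(rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$reject <- !is.na(out$p_adj) & out$p_adj <= q
  out
}

#' Pre-switch test on embedded coordinates
#'
#' Rank-sum comparison of the embedded coordinates of pre-switch trials
#' (the last complete triplet before each button press, labelled by the
#' percept switched *into*), pooled across subjects. Requires at least two
#' switches into each percept.
#'
#' @param embeddings A `trial_embedding` (from pre-switch epochs) or list
#'   of them.
#' @return A one-row tibble: `n_into_1`, `n_into_2`, `p`.
#' @export
switch_test <- function(embeddings) {
  if (inherits(embeddings, "trial_embedding")) embeddings <- list(embeddings)
  coord <- unlist(lapply(embeddings, function(e) e$coord))
  lab <- unlist(lapply(embeddings, function(e) e$label))
  ok <- !is.na(lab)
  n1 <- sum(lab[ok] == "1-stream")
  n2 <- sum(lab[ok] == "2-stream")
  if (n1 < 2 || n2 < 2) {
    stopf("Too few switches for the pre-switch test (%d into 1-stream, %d into 2-stream).",
          n1, n2)
  }
  tibble::tibble(
    n_into_1 = n1, n_into_2 = n2,
    p = ranksum_embedding(coord[ok], lab[ok])
  )
}
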