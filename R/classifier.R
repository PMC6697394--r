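# Trial-level percept classification: 50-ms bin features, F-score ranking,
# recursive feature selection with a linear SVM, class balancing by
# undersampling, and balanced test accuracy over repeated random splits.

#' Bin triplet epochs into 50-ms mean-LFP features
#'
#' The feature space is the collection of `n_bins` non-overlapping time bins
#' (default 12 x 50 ms, spanning the 600 ms triplet) at all recording sites;
#' the feature value is the mean LFP over the bin. Trials without a percept
#' label, or masked at any site, are dropped so features stay aligned.
#'
#' @param ep A labelled [labeled_epochs()] object with window `(0, dur, 0)`.
#' @param bin_ms Bin width (ms); must divide the epoch duration.
#' @return A list of class `feature_table`: `x` (trial x feature matrix),
#'   `labels` (percept class 1/2 per trial), `map` (tibble: feature, site,
#'   area, bin, bin_start_ms), `trial_onsets`.
#' @export
bin_features <- function(ep, bin_ms = 50) {
  stopifnot(inherits(ep, "labeled_epochs"))
  if (ep$window[1] != 0 || ep$window[3] != 0) {
    stopf("Features are defined on the bare triplet window (pre = post = 0).")
  }
  d <- dim(ep$trials)
  samp_per_bin <- bin_ms / 1000 * ep$fs
  if (samp_per_bin != round(samp_per_bin) ||
    d[3] %% samp_per_bin != 0) {
    stopf("Bin width %g ms does not divide the %d-sample epoch.",
          bin_ms, d[3])
  }
  n_bins <- d[3] / samp_per_bin
  cls <- percept_class(ep$labels)
  keep <- !is.na(cls) & apply(ep$kept, 1, all)
  idx <- which(keep)
  bin_of <- rep(seq_len(n_bins), each = samp_per_bin)
  x <- matrix(0, length(idx), d[2] * n_bins)
  for (i in seq_along(idx)) {
    m <- ep$trials[idx[i], , , drop = TRUE] # site x time
    if (is.null(dim(m))) m <- matrix(m, nrow = d[2])
    bm <- t(apply(m, 1, function(v) tapply(v, bin_of, mean)))
    x[i, ] <- as.vector(t(bm)) # feature order: site-major, bin-minor
  }
  map <- tibble::tibble(
    feature = seq_len(d[2] * n_bins),
    site = rep(ep$sites$site, each = n_bins),
    area = rep(ep$sites$area, each = n_bins),
    bin = rep(seq_len(n_bins), d[2]),
    bin_start_ms = rep((seq_len(n_bins) - 1) * bin_ms, d[2])
  )
  structure(
    list(
      x = x, labels = cls[idx], map = map,
      trial_onsets = ep$trial_onsets[idx]
    ),
    class = "feature_table"
  )
}

#' F score of a feature for class separation
#'
#' Ratio of the between-class squared deviations of the class means from the
#' overall mean to the sum of the within-class sample variances:
#' `F = ((m1 - m)^2 + (m2 - m)^2) / (v1 + v2)`. Features whose within-class
#' variance vanishes in both classes while the means differ get `Inf` (ranked
#' first); identical constant classes get 0.
#'
#' @param x Feature values.
#' @param y Class labels (two classes).
#' @return The F score (nonnegative, possibly `Inf`).
#' @export
f_score <- function(x, y) {
  cls <- sort(unique(y))
  if (length(cls) != 2) stopf("F score needs exactly two classes.")
  x1 <- x[y == cls[1]]
  x2 <- x[y == cls[2]]
  m <- mean(x)
  num <- (mean(x1) - m)^2 + (mean(x2) - m)^2
  den <- var(x1) + var(x2)
  if (den == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  num / den
}

# Column-wise F scores of a feature matrix.
f_scores <- function(x, y) {
  apply(x, 2, f_score, y = y)
}

#' Balance a training set by undersampling the majority class
#'
#' Randomly subsamples the majority class down to the minority class size so
#' the classifier trains on an unbiased set (observed class imbalances run
#' up to about 1:3).
#'
#' @param x Trial x feature matrix.
#' @param y Class labels.
#' @param seed Integer seed.
#' @return List with balanced `x` and `y`.
#' @export
balance_training <- function(x, y, seed = 1L) {
  cls <- sort(unique(y))
  if (length(cls) != 2) stopf("Balancing needs exactly two classes.")
  n <- table(factor(y, levels = cls))
  if (any(n < 5)) stopf("Each class needs at least 5 trials (have %d, %d).",
                        n[1], n[2])
  with_seed(seed, {
    keep <- unlist(lapply(cls, function(cl) {
      i <- which(y == cl)
      if (length(i) > min(n)) sample(i, min(n)) else i
    }))
    keep <- sort(keep)
    list(x = x[keep, , drop = FALSE], y = y[keep])
  })
}

#' Balanced classification accuracy
#'
#' Mean of the per-class correct-classification fractions; insensitive to
#' class imbalance in the test set (a majority-vote predictor scores 0.5).
#'
#' @param pred Predicted labels.
#' @param truth True labels (both classes present).
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(pred, truth) {
  cls <- sort(unique(truth))
  if (length(cls) < 2) stopf("Both classes must appear in `truth`.")
  mean(vapply(cls, function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1)))
}

# Stratified subtrain/validation split; resplits if a side is single-class.
stratified_split <- function(y, val_frac) {
  for (i in 1:100) {
    val <- unlist(lapply(sort(unique(y)), function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1L, round(val_frac * length(idx))))
    }))
    tr <- setdiff(seq_along(y), val)
    if (length(unique(y[tr])) == 2 && length(unique(y[val])) == 2) {
      return(list(train = tr, val = val))
    }
  }
  stopf("Could not produce a two-class subtrain/validation split.")
}

#' Recursive F-score feature selection with an SVM
#'
#' Ranks features by F score on the training set and keeps the top `d`.
#' Then, for `k = d, d-1, ..., 1` (dropping the lowest-F feature at each
#' step), the training set is split into subtraining and validation parts
#' (5 random stratified 80/20 splits) and a linear SVM is fit on the top-k
#' features; the mean validation error is recorded. The optimal dimension
#' `d_star` is the smallest `k` attaining the minimum mean validation error;
#' the final model is refit on the full training set with the top `d_star`
#' features.
#'
#' @param x Training trial x feature matrix.
#' @param y Training labels.
#' @param d Initial number of features (10% of the training-set size in the
#'   full pipeline).
#' @param n_splits Internal validation repeats per `k`.
#' @param val_frac Validation fraction of each internal split.
#' @param cost SVM cost parameter.
#' @param seed Integer seed.
#' @return List: `d_star`, `features` (column indices of the selected
#'   features, best first), `model` (fitted [e1071::svm]), `val_error`
#'   (mean validation error per `k`, names = k).
#' @export
recursive_select_and_train <- function(x, y, d, n_splits = 5,
                                       val_frac = 0.2, cost = 1,
                                       seed = 1L) {
  stopifnot(d >= 1)
  d <- min(d, ncol(x))
  with_seed(seed, {
    rank <- order(f_scores(x, y), decreasing = TRUE)
    top <- rank[seq_len(d)]
    val_err <- numeric(d)
    names(val_err) <- as.character(seq_len(d))
    for (k in d:1) {
      feats <- top[seq_len(k)]
      errs <- numeric(n_splits)
      for (r in seq_len(n_splits)) {
        sp <- stratified_split(y, val_frac)
        fit <- e1071::svm(
          x = x[sp$train, feats, drop = FALSE],
          y = factor(y[sp$train]),
          kernel = "linear", cost = cost, scale = FALSE
        )
        pred <- predict(fit, x[sp$val, feats, drop = FALSE])
        errs[r] <- mean(pred != factor(y[sp$val], levels = levels(pred)))
      }
      val_err[k] <- mean(errs)
    }
    d_star <- min(which(val_err == min(val_err)))
    features <- top[seq_len(d_star)]
    model <- e1071::svm(
      x = x[, features, drop = FALSE], y = factor(y),
      kernel = "linear", cost = cost, scale = FALSE
    )
    list(d_star = d_star, features = features, model = model,
         val_error = val_err)
  })
}

# Per-set z-scaling of feature columns (own mean/SD; zero-SD columns -> 0).
zscale_columns <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(x, 2, mu), 2, sdv, `/`)
}

#' Repeated feature-selection + SVM percept classification
#'
#' Each repetition draws a random four-fifths training / one-fifth test
#' split, z-scales each feature over the training and test sets separately,
#' balances the training set by undersampling, keeps the top
#' `D = ceiling(0.1 * training size)` features by F score, runs the
#' recursive selection of [recursive_select_and_train()], and scores the
#' held-out test set with balanced accuracy. Feature-selection probabilities
#' are tallied over repetitions; features above `prob_thresh` (default 0.3)
#' define the classifier-driven site map.
#'
#' @param ft A [bin_features()] table.
#' @param n_rep Number of repetitions.
#' @param train_frac Training fraction of each split.
#' @param prob_thresh Selection-probability threshold for the map.
#' @param cost SVM cost parameter.
#' @param seed Integer seed.
#' @return A list of class `percept_classifier`: `accuracy` (length
#'   `n_rep`), `feature_prob` (map tibble + `probability`), `map_sites`
#'   (sites with any feature above threshold), `d_star` (per repetition),
#'   and the call parameters.
#' @export
run_classification <- function(ft, n_rep = 100, train_frac = 0.8,
                               prob_thresh = 0.3, cost = 1, seed = 1L) {
  stopifnot(inherits(ft, "feature_table"))
  n <- nrow(ft$x)
  if (length(unique(ft$labels)) != 2) {
    stopf("Both percept classes must be present.")
  }
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_rep))
  acc <- numeric(n_rep)
  d_star <- integer(n_rep)
  sel_count <- numeric(ncol(ft$x))
  for (r in seq_len(n_rep)) {
    res <- with_seed(rep_seeds[r], {
      test <- sort(sample.int(n, max(2L, round((1 - train_frac) * n))))
      train <- setdiff(seq_len(n), test)
      if (length(unique(ft$labels[test])) < 2 ||
        length(unique(ft$labels[train])) < 2) {
        # resample a split containing both classes on both sides
        repeat {
          test <- sort(sample.int(n, max(2L, round((1 - train_frac) * n))))
          train <- setdiff(seq_len(n), test)
          if (length(unique(ft$labels[test])) == 2 &&
            length(unique(ft$labels[train])) == 2) {
            break
          }
        }
      }
      xtr <- zscale_columns(ft$x[train, , drop = FALSE])
      xte <- zscale_columns(ft$x[test, , drop = FALSE])
      bal <- balance_training(xtr, ft$labels[train],
        seed = sample.int(.Machine$integer.max, 1)
      )
      d <- ceiling(0.1 * length(bal$y))
      sel <- recursive_select_and_train(bal$x, bal$y, d,
        cost = cost,
        seed = sample.int(.Machine$integer.max, 1)
      )
      pred <- as.integer(as.character(
        predict(sel$model, xte[, sel$features, drop = FALSE])
      ))
      list(
        acc = balanced_accuracy(pred, ft$labels[test]),
        features = sel$features, d_star = sel$d_star
      )
    })
    acc[r] <- res$acc
    d_star[r] <- res$d_star
    sel_count[res$features] <- sel_count[res$features] + 1
  }
  fp <- ft$map
  fp$probability <- sel_count / n_rep
  map_sites <- sort(unique(fp$site[fp$probability > prob_thresh]))
  structure(
    list(
      accuracy = acc, feature_prob = fp, map_sites = map_sites,
      d_star = d_star, n_rep = n_rep, train_frac = train_frac,
      prob_thresh = prob_thresh, cost = cost, seed = seed
    ),
    class = "percept_classifier"
  )
}

#' @export
print.percept_classifier <- function(x, ...) {
  cat(sprintf(
    "percept_classifier: %d repetitions, balanced accuracy mean %.3f / median %.3f\n",
    x$n_rep, mean(x$accuracy), median(x$accuracy)
  ))
  cat(sprintf(
    "  %d features above selection probability %.2f at %d sites\n",
    sum(x$feature_prob$probability > x$prob_thresh), x$prob_thresh,
    length(x$map_sites)
  ))
  invisible(x)
}
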