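test_that("feature binning averages 50-ms windows site by site", {
  # constant trials map to constant features
  arr <- array(3.5, dim = c(4, 2, 600))
  ep <- epochs_from_array(arr, rep(c("1-stream", "2-stream"), 2))
  ft <- bin_features(ep)
  expect_equal(dim(ft$x), c(4, 24)) # 12 bins x 2 sites
  expect_true(all(ft$x == 3.5))
  # a 0..599 ramp has bin means 24.5, 74.5, ..., 574.5
  arr2 <- array(0, dim = c(2, 1, 600))
  arr2[1, 1, ] <- 0:599
  arr2[2, 1, ] <- 0:599
  ft2 <- bin_features(epochs_from_array(arr2, c("1-stream", "2-stream")))
  expect_equal(as.numeric(ft2$x[1, ]), seq(24.5, 574.5, by = 50))
  expect_equal(ncol(ft2$x), 12)
  # masked site-trials drop the trial
  ep$kept[2, 1] <- FALSE
  expect_equal(nrow(bin_features(ep)$x), 3)
  # non-bare windows are rejected
  ep700 <- epochs_from_array(array(0, c(2, 1, 2000)),
                             c("1-stream", "2-stream"),
                             window = c(700, 600, 700))
  expect_error(bin_features(ep700), "bare triplet")
})

test_that("the F score follows its definition and is monotone in separation", {
  s <- 1 / sqrt(2)
  x <- c(-1 - s, -1 + s, 1 - s, 1 + s) # class means -1/+1, within-var 1 each
  y <- c(1, 1, 2, 2)
  expect_equal(f_score(x, y), 1)
  withr::local_seed(13)
  x0 <- rnorm(200)
  y0 <- rep(1:2, 100)
  expect_lt(f_score(x0, y0), 0.1) # identical class distributions
  seps <- c(0.5, 1, 2, 4)
  base <- rnorm(100)
  fs <- sapply(seps, function(d) {
    f_score(c(base, base + d), rep(1:2, each = 100))
  })
  expect_true(all(diff(fs) > 0))
  # zero within-class variance with distinct means ranks first
  expect_equal(f_score(c(0, 0, 1, 1), c(1, 1, 2, 2)), Inf)
  expect_equal(f_score(c(2, 2, 2, 2), c(1, 1, 2, 2)), 0)
  expect_error(f_score(1:4, rep(1, 4)), "two classes")
})

test_that("training sets are balanced by undersampling the majority class", {
  withr::local_seed(14)
  x <- matrix(rnorm(400 * 3), 400)
  y <- rep(c(1, 2), c(300, 100))
  bal <- balance_training(x, y, seed = 5)
  expect_equal(as.numeric(table(bal$y)), c(100, 100))
  expect_true(all(bal$x[bal$y == 2, 1] %in% x[y == 2, 1]))
  # already balanced input is unchanged
  xb <- matrix(rnorm(40), 20)
  yb <- rep(c(1, 2), 10)
  bal2 <- balance_training(xb, yb, seed = 5)
  expect_equal(bal2$x, xb)
  # deterministic under seed
  expect_equal(balance_training(x, y, seed = 9), balance_training(x, y, seed = 9))
  expect_error(balance_training(x[1:8, ], rep(c(1, 2), c(4, 4)), 1), "at least 5")
})

test_that("balanced accuracy averages per-class recall", {
  truth <- rep(c(1, 2), each = 10)
  pred <- truth
  pred[11:15] <- 1 # TNR 0.5, TPR 1
  expect_equal(balanced_accuracy(pred, truth), 0.75)
  expect_equal(balanced_accuracy(truth, truth), 1)
  truth9 <- rep(c(1, 2), c(90, 10))
  expect_equal(balanced_accuracy(rep(1, 100), truth9), 0.5)
  expect_error(balanced_accuracy(rep(1, 4), rep(1, 4)), "Both classes")
})

test_that("recursive selection keeps informative features and prunes noise", {
  withr::local_seed(15)
  informative <- 0
  small <- 0
  top_ranked <- 0
  for (r in 1:10) {
    n <- 240
    x <- matrix(rnorm(n * 50), n)
    y <- rep(c(1, 2), each = n / 2)
    x[y == 2, 1] <- x[y == 2, 1] + 5
    x[y == 2, 2] <- x[y == 2, 2] + 5
    sel <- recursive_select_and_train(x, y, d = 12, seed = r)
    if (sel$d_star <= 5) small <- small + 1
    # with this separation one informative feature can already be enough;
    # what must hold is that noise features do not displace informative ones
    if (all(sel$features %in% c(1, 2))) informative <- informative + 1
    if (sel$features[1] %in% c(1, 2)) top_ranked <- top_ranked + 1
  }
  expect_gte(small, 9)
  expect_gte(informative, 9)
  expect_equal(top_ranked, 10)
})

test_that("all-noise features give chance-level validation error", {
  withr::local_seed(16)
  x <- matrix(rnorm(100 * 20), 100)
  y <- rep(c(1, 2), 50)
  sel <- recursive_select_and_train(x, y, d = 8, seed = 2)
  expect_true(all(sel$val_error > 0.25 & sel$val_error < 0.75))
  # d = 1 forces d_star = 1
  sel1 <- recursive_select_and_train(x, y, d = 1, seed = 3)
  expect_equal(sel1$d_star, 1)
  expect_equal(length(sel1$features), 1)
})

make_feature_table <- function(n = 120, n_feat = 24, informative = 1:2,
                               sep = 3, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * n_feat), n)
    y <- rep(c(1L, 2L), each = n / 2)
    for (f in informative) x[y == 2, f] <- x[y == 2, f] + sep
    n_sites <- n_feat / 12
    structure(
      list(
        x = x, labels = y,
        map = tibble::tibble(
          feature = seq_len(n_feat),
          site = rep(seq_len(n_sites), each = 12),
          area = "HGPM",
          bin = rep(1:12, n_sites),
          bin_start_ms = rep(0:11 * 50, n_sites)
        ),
        trial_onsets = (seq_len(n) - 1) * 0.6
      ),
      class = "feature_table"
    )
  })
}

test_that("classification separates labelled classes and finds their features", {
  ft <- make_feature_table(sep = 3, seed = 21)
  clf <- run_classification(ft, n_rep = 12, seed = 4)
  expect_gt(median(clf$accuracy), 0.85)
  probs <- clf$feature_prob$probability
  expect_true(all(probs[1:2] > 0.3))
  expect_s3_class(autoplot(clf), "ggplot")
  expect_equal(glance(clf)$n_rep, 12)
  expect_equal(nrow(tidy(clf)), 24)
})

test_that("classification is at chance on unstructured data", {
  ft <- make_feature_table(informative = integer(0), seed = 22)
  clf <- run_classification(ft, n_rep = 12, seed = 5)
  expect_gt(
    stats::t.test(clf$accuracy, mu = 0.5, alternative = "greater")$p.value,
    0.05
  )
})

test_that("the classification pipeline is deterministic and scale-invariant", {
  ft <- make_feature_table(sep = 2, seed = 23)
  a <- run_classification(ft, n_rep = 6, seed = 9)
  b <- run_classification(ft, n_rep = 6, seed = 9)
  expect_identical(a$accuracy, b$accuracy)
  # per-feature affine transforms are absorbed by the per-set z-scaling
  ft2 <- ft
  withr::local_seed(24)
  ft2$x <- sweep(sweep(ft$x, 2, runif(24, 0.5, 3), `*`), 2, rnorm(24), `+`)
  c <- run_classification(ft2, n_rep = 6, seed = 9)
  expect_equal(a$accuracy, c$accuracy, tolerance = 1e-8)
  # train and test never share trials
  expect_true(max(a$accuracy) <= 1 && min(a$accuracy) >= 0)
})
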