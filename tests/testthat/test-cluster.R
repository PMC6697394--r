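test_that("pointwise t matches stats::t.test with pooled variance", {
  ep <- two_class_epochs(n_per_class = 15, n_time = 40, seed = 2)
  pw <- pointwise_t(ep)
  cls <- ep$labels
  for (tau in c(1, 17, 40)) {
    ref <- stats::t.test(
      ep$trials[cls == "1-stream", 1, tau],
      ep$trials[cls == "2-stream", 1, tau],
      var.equal = TRUE
    )
    expect_equal(pw$tmat[1, tau], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(pw$praw[1, tau], ref$p.value, tolerance = 1e-10)
  }
})

test_that("pointwise t is near-null on exchangeable data and huge on offsets", {
  ep <- two_class_epochs(n_per_class = 200, n_time = 300, seed = 3)
  pw <- pointwise_t(ep)
  expect_lt(abs(mean(pw$praw[1, ] < 0.05) - 0.05), 0.035)
  ep2 <- two_class_epochs(
    n_per_class = 200, n_time = 100, offset = 10,
    offset_range = 41:60, seed = 4
  )
  pw2 <- pointwise_t(ep2)
  expect_true(all(abs(pw2$tmat[1, 41:60]) > 50))
})

test_that("degenerate zero-variance points are marked untestable", {
  arr <- array(1, dim = c(4, 1, 30))
  ep <- epochs_from_array(arr, rep(c("1-stream", "2-stream"), 2))
  pw <- pointwise_t(ep)
  expect_true(all(is.na(pw$tmat[1, ])))
  expect_true(pw$testable[1]) # class counts fine; points are the issue
  # a site with an empty class is flagged untestable
  ep$labels <- rep("1-stream", 4)
  expect_false(pointwise_t(ep)$testable[1])
})

test_that("cluster formation enforces length, sign and adjacency rules", {
  n <- 60
  t25 <- rep(0, n)
  t25[10:34] <- 3
  p <- ifelse(t25 != 0, 0.01, 0.9)
  cl <- form_clusters(t25, p, min_len = 20)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$start, 10)
  expect_equal(cl$end, 34)
  expect_equal(cl$mass, 25 * 3)
  # 15 consecutive significant points: below min_len
  t15 <- rep(0, n)
  t15[1:15] <- 3
  expect_equal(nrow(form_clusters(t15, ifelse(t15 != 0, 0.01, 0.9), 20)), 0)
  # sign flip splits a run: 12 + 13 both below 20
  tflip <- rep(0, n)
  tflip[10:34] <- 3
  tflip[21:34] <- -3
  expect_equal(
    nrow(form_clusters(tflip, ifelse(tflip != 0, 0.01, 0.9), 20)), 0
  )
})

test_that("cluster formation agrees with a brute-force scan on random cases", {
  withr::local_seed(7)
  for (rep in 1:200) {
    n <- sample(30:120, 1)
    tvec <- rnorm(n, sd = 2)
    pvec <- 2 * pt(-abs(tvec), df = 30)
    ml <- sample(c(1, 3, 5, 10), 1)
    got <- form_clusters(tvec, pvec, min_len = ml)
    want <- brute_clusters(tvec, pvec, min_len = ml)
    expect_equal(nrow(got), length(want))
    for (i in seq_along(want)) {
      expect_equal(got$start[i], unname(want[[i]]["start"]))
      expect_equal(got$end[i], unname(want[[i]]["end"]))
      expect_equal(got$mass[i], unname(want[[i]]["mass"]))
    }
  }
})

test_that("cluster mass is the plain sum of member t scores", {
  tvec <- c(2.5, 2.5, 2.5, -3, -3)
  expect_equal(cluster_mass(tvec, 1, 3), 7.5)
  expect_equal(cluster_mass(tvec, 4, 5), -6)
  withr::local_seed(8)
  for (i in 1:20) {
    tv <- rnorm(50)
    a <- sample(1:40, 1)
    b <- a + sample(0:9, 1)
    expect_equal(cluster_mass(tv, a, b), sum(tv[a:b]))
  }
})

test_that("Monte-Carlo p follows (r + 1) / (n + 1) and never reaches 0", {
  null <- rep(5, 10) # |null| >= |obs| always
  expect_equal(monte_carlo_p(4, null), 1)
  expect_equal(monte_carlo_p(1e9, numeric(10000) + 0), 1 / 10001)
  null2 <- c(rep(10, 499), rep(0, 9500)) # r = 499, n = 9999
  expect_equal(monte_carlo_p(9, null2), 0.05)
  expect_gt(monte_carlo_p(Inf, rnorm(100)), 0)
})

test_that("cluster p values spread over members, 1 elsewhere", {
  cl <- tibble::tibble(start = 60, end = 130, sign = 1, mass = 100, p = 0.01)
  p <- assign_adjusted_p(cl, 600)
  expect_true(all(p[60:130] == 0.01))
  expect_true(all(p[-(60:130)] == 1))
  expect_true(all(assign_adjusted_p(cl[0, ], 100) == 1))
  two <- tibble::tibble(
    start = c(10, 50), end = c(30, 90), sign = c(1, -1),
    mass = c(40, -80), p = c(0.03, 0.2)
  )
  p2 <- assign_adjusted_p(two, 100)
  expect_equal(unique(p2[10:30]), 0.03)
  expect_equal(unique(p2[50:90]), 0.2)
})

test_that("BH selection matches a brute-force step-up on random p vectors", {
  bh_oracle <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= q * seq_len(m) / m)
    rej <- logical(m)
    if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  expect_equal(
    fdr_across_sites(c(0.001, 0.2, 0.9), q = 0.01),
    c(TRUE, FALSE, FALSE)
  )
  expect_false(any(fdr_across_sites(rep(1, 20), q = 0.01)))
  expect_true(all(fdr_across_sites(rep(1e-6, 50), q = 0.01)))
  withr::local_seed(9)
  for (i in 1:300) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_equal(fdr_across_sites(p, q), bh_oracle(p, q))
  }
})

test_that("label-invariant data yields an all-zero permutation null", {
  arr <- array(rep(rnorm(80), each = 12), dim = c(12, 1, 80))
  ep <- epochs_from_array(arr, rep(c("1-stream", "2-stream"), 6))
  null <- permutation_null(ep, 1, n_perm = 50, min_len = 5, seed = 3)
  expect_true(all(null == 0))
})

test_that("the permutation null is reproducible under a fixed seed", {
  ep <- two_class_epochs(n_per_class = 12, n_time = 60, seed = 10)
  # permissive clustering so most permutations yield a nonzero statistic
  a <- permutation_null(ep, 1, n_perm = 200, min_len = 2, alpha = 0.3,
                        seed = 77)
  b <- permutation_null(ep, 1, n_perm = 200, min_len = 2, alpha = 0.3,
                        seed = 77)
  expect_identical(a, b)
  expect_gt(sum(a != 0), 100)
  c <- permutation_null(ep, 1, n_perm = 200, min_len = 2, alpha = 0.3,
                        seed = 78)
  expect_false(identical(a, c))
})

test_that("observed statistics are invariant to trial order", {
  ep <- two_class_epochs(
    n_per_class = 20, n_time = 80, offset = 2,
    offset_range = 21:50, seed = 11
  )
  perm <- withr::with_seed(1, sample(40))
  ep2 <- ep
  ep2$trials <- ep$trials[perm, , , drop = FALSE]
  ep2$labels <- ep$labels[perm]
  ep2$kept <- ep$kept[perm, , drop = FALSE]
  a <- pointwise_t(ep)
  b <- pointwise_t(ep2)
  expect_equal(a$tmat, b$tmat)
  expect_equal(
    form_clusters(a$tmat[1, ], a$praw[1, ], 10),
    form_clusters(b$tmat[1, ], b$praw[1, ], 10)
  )
})

test_that("the full site map localizes an injected effect", {
  sb <- mini_block(
    n_triplets = 200, n_sites = 4, effect_sites = c(1, 2),
    effect_amp = 60, noise_sd = 15, mean_dur = 20, rt_mean = 0, seed = 12,
    artifact_rate = 0
  )
  ep <- epoch_triplets(sb$block)
  ep <- reject_trials(ep)
  ep$labels <- sb$ground_truth$true_percept
  map <- aep_cluster_test(ep, n_perm = 400, seed = 5)
  expect_s3_class(map, "site_stat_map")
  expect_true(all(map$p_site[1:2] < 0.05))
  # best cluster overlaps the injected 210-280 ms window
  expect_true(all(map$best_start_ms[1:2] < 280))
  expect_true(all(map$best_end_ms[1:2] > 210))
  td <- tidy(map)
  expect_true(all(c("site", "start_ms", "end_ms", "mass", "p") %in% names(td)))
  g <- glance(map)
  expect_equal(g$n_sites, 4)
  expect_s3_class(autoplot(map), "ggplot")
})
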