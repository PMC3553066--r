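test_that("ARI is 1 for identical partitions and -0.5 for the crossed pair", {
  set.seed(13)
  for (rep in 1:25) {
    k <- sample(1:4, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(k, k), 1)
  }
  k <- c(a = 1, b = 1, c = 2, d = 2)
  l <- c(a = 1, b = 2, c = 1, d = 2)
  expect_equal(adjusted_rand_index(k, l), -0.5)
  expect_equal(oracle_ari(k, l), -0.5)
})

test_that("ARI matches the brute-force pair-count oracle and mclust", {
  set.seed(14)
  for (rep in 1:40) {
    n <- sample(5:15, 1)
    k <- sample(1:4, n, replace = TRUE)
    l <- sample(1:3, n, replace = TRUE)
    expect_equal(adjusted_rand_index(k, l), oracle_ari(k, l), tolerance = 1e-12)
    expect_equal(adjusted_rand_index(k, l), mclust::adjustedRandIndex(k, l),
                 tolerance = 1e-12)
  }
})

test_that("ARI is symmetric and invariant to cluster relabelling", {
  set.seed(15)
  for (rep in 1:20) {
    k <- sample(1:3, 10, replace = TRUE)
    l <- sample(1:4, 10, replace = TRUE)
    expect_equal(adjusted_rand_index(k, l), adjusted_rand_index(l, k))
    relab <- sample(10:13)[k]                 # bijective relabelling
    expect_equal(adjusted_rand_index(relab, l), adjusted_rand_index(k, l))
  }
})

test_that("ARI handles degenerate and mismatched partitions", {
  expect_equal(adjusted_rand_index(rep(1, 5), rep(2, 5)), 1)   # identical: one cluster
  expect_equal(adjusted_rand_index(1:5, 1:5), 1)               # identical: singletons
  expect_equal(adjusted_rand_index(rep(1, 5), c(1, 1, 1, 1, 2)), 0)
  expect_error(adjusted_rand_index(c(a = 1, b = 2), c(a = 1, x = 2)),
               "different sample sets")
  expect_error(adjusted_rand_index(1:4, 1:5), "different lengths")
})

test_that("mean ARI over an exhaustive relabelling null is exactly zero", {
  k <- c(1, 1, 1, 2, 2, 3)                    # cluster sizes (3, 2, 1)
  base_l <- c(1, 1, 1, 2, 2, 3)
  scores <- vapply(all_perms(1:6), function(p) adjusted_rand_index(k, base_l[p]),
                   numeric(1))
  expect_equal(mean(scores), 0, tolerance = 1e-12)
})

test_that("variance selection ranks by variance with stable ties", {
  x <- make_matrix(rbind(c(1, 1, 1, 1), c(0, 2, 0, 2)), 2)
  expect_equal(variance_select(x, 1)$features, "f02")   # var 4/3 beats 0
  set.seed(16)
  x2 <- make_matrix(matrix(rnorm(100 * 8), 100, 8), 3)
  sel <- variance_select(x2, 100)
  v <- apply(x2$values, 1, var)
  expect_equal(sel$features, rownames(x2$values)[order(-v)])
  # a constant feature is never selected while non-constant features remain
  x3 <- make_matrix(rbind(rep(5, 6), matrix(rnorm(18), 3, 6)), 2)
  expect_false("f01" %in% variance_select(x3, 3)$features)
})

test_that("COPA ranking favours spikes and ignores per-feature offsets", {
  m <- rbind(spike = c(rep(0.5, 4), rep(0.5, 9), 12),    # one huge tumour value
             flat = c(rep(0.6, 4), rep(1.4, 10)))        # uniformly moderate
  m <- m + matrix(seq(-0.2, 0.2, length.out = 14)[sample(14)], 2, 14, byrow = TRUE)
  x <- make_matrix(m, 4)
  sel <- copa_rank_select(x, k = 1)
  expect_equal(sel$features, "spike")
  # k = all features returns everything, ordered by score
  all_sel <- copa_rank_select(x, k = 2)
  expect_equal(length(all_sel$features), 2L)
  # adding a constant to one feature leaves the ranking unchanged
  m2 <- m; m2["flat", ] <- m2["flat", ] + 100
  expect_equal(copa_rank_select(make_matrix(m2, 4), k = 2)$features,
               all_sel$features)
})

test_that("DE selection agrees with per-feature t.test + hand-coded BH", {
  set.seed(18)
  m <- matrix(rnorm(40 * 16), 40, 16)
  m[1:5, 9:16] <- m[1:5, 9:16] + 5          # truly shifted features
  x <- make_matrix(m, 8)
  alpha <- 0.05
  sel <- de_select(x, alpha = alpha)
  # oracle: stats::t.test per row, BH by the step-up formula
  p <- apply(m, 1, function(r) stats::t.test(r[1:8], r[9:16])$p.value)
  n <- length(p)
  ord <- order(p)
  adj <- rev(cummin(rev(p[ord] * n / seq_len(n))))
  padj <- numeric(n); padj[ord] <- pmin(adj, 1)
  expect_setequal(sel$features, features(x)[padj < alpha])
  expect_true(all(sprintf("f%02d", 1:5) %in% sel$features))
})

test_that("DE selection is monotone in alpha and handles degenerate rows", {
  set.seed(20)
  x <- make_matrix(matrix(rnorm(30 * 10), 30, 10), 5)
  expect_length(de_select(x, alpha = 1)$features, 30L)
  expect_length(de_select(x, alpha = 1e-12)$features, 0L)
  flat <- make_matrix(rbind(rep(1, 10), c(rep(0, 5), rep(3, 5))), 5)
  sel <- de_select(flat, alpha = 0.01)
  expect_false("f01" %in% sel$features)     # identical means, zero variance
  expect_true("f02" %in% sel$features)      # zero variance, huge shift
})

test_that("clustering separates well-separated blobs and is seed-deterministic", {
  set.seed(22)
  blob <- cbind(matrix(rnorm(5 * 8, 0, 0.2), 5, 8),
                matrix(rnorm(5 * 7, 6, 0.2), 5, 7))
  colnames(blob) <- paste0("s", 1:15)
  truth <- rep(1:2, c(8, 7))
  for (method in c("kmeans", "pam")) {
    part <- cluster_samples(blob, method, n_clusters = 2, seed = 5)
    expect_equal(adjusted_rand_index(part, truth), 1)
  }
  p1 <- cluster_samples(blob, "kmeans", 2, seed = 99)
  p2 <- cluster_samples(blob, "kmeans", 2, seed = 99)
  expect_identical(p1, p2)
  expect_error(cluster_samples(blob, "kmeans", 16), "between 2 and")
})

test_that("multi-start k-means is at least as good as each single start", {
  set.seed(24)
  m <- matrix(rnorm(6 * 24), 6, 24)
  colnames(m) <- paste0("s", 1:24)
  best <- cluster_samples(m, "kmeans", 4, n_repeats = 20, seed = 1)
  best_wss <- wss_of(m, best)
  for (s in 2:6) {
    single <- cluster_samples(m, "kmeans", 4, n_repeats = 1, seed = s)
    expect_lte(best_wss, wss_of(m, single) + 1e-8)
  }
})

test_that("Kruskal-Wallis matches the hand-ranked statistic", {
  # groups (1,2,3) vs (4,5,6): ranks 1..6, H = 12/(6*7) * (36/3 + 225/3) - 21
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(unname(kw["H"]), 27 / 7, tolerance = 1e-12)
  expect_equal(unname(kw["p"]),
               stats::pchisq(27 / 7, df = 1, lower.tail = FALSE))
  expect_equal(kruskal_wallis(list(rep(2, 4), rep(2, 3))), c(H = 0, p = 1))
  # permuting within groups changes nothing
  kw2 <- kruskal_wallis(list(c(3, 1, 2), c(6, 4, 5)))
  expect_equal(kw2, kw)
  expect_error(kruskal_wallis(list(1:3)), "2 non-empty")
})

test_that("a perfectly structured dataset scores ARI 1 for every selector", {
  cfg <- simulation_config(n_features = 600, n_normal = 6, n_tumour = 20,
                           subtype_sizes = c(10, 10), n_outlier_features = 60,
                           outlier_delta = 6, outlier_sample_fraction = 0.2,
                           subtype_specific_fraction = 1,
                           n_de_features = 0, n_noise_features = 0, seed = 77)
  sim <- generate_expression(cfg)
  labels <- attr(sim$truth, "subtype_map")
  labels <- stats::setNames(as.character(labels), names(labels))
  # k-means recovers the planted subtypes perfectly from either selection;
  # PAM's medoid criterion is not suited to minority-event (outlier) signal,
  # whose within-subtype distances stay large, so it is checked on separable
  # blobs elsewhere instead
  ari <- evaluate_selection(sim$matrix, labels,
                            methods = c("mcopa", "variance"),
                            clusterers = "kmeans",
                            variance_k = 60, seed = 3)
  expect_equal(dim(ari), c(2L, 1L))
  expect_true(all(ari == 1))
})

test_that("clustering against shuffled labels scores near zero on average", {
  cfg <- simulation_config(n_features = 200, n_normal = 5, n_tumour = 16,
                           subtype_sizes = c(8, 8), n_outlier_features = 0,
                           n_de_features = 0, n_noise_features = 0, seed = 88)
  sim <- generate_expression(cfg)
  tum <- sim$matrix$values[, -(1:5)]
  part <- cluster_samples(tum, "kmeans", 2, seed = 4)
  set.seed(90)
  scores <- replicate(200, adjusted_rand_index(part, sample(rep(1:2, 8))))
  expect_lt(abs(mean(scores)), 0.05)
})

test_that("selector/clusterer grids have the requested dimensions", {
  cfg <- simulation_config(n_features = 400, seed = 99)
  sim <- generate_expression(cfg)
  smap <- attr(sim$truth, "subtype_map")
  labels <- stats::setNames(as.character(smap), names(smap))
  ari <- evaluate_selection(sim$matrix, labels,
                            methods = c("mcopa", "copa", "de", "variance"),
                            clusterers = "kmeans", variance_k = 100, seed = 7)
  expect_equal(rownames(ari), c("mcopa", "copa", "de", "variance"))
  expect_equal(colnames(ari), "kmeans")
  sels <- attr(ari, "selections")
  # COPA ranking is sized to the outlier selection
  expect_equal(length(sels$copa), max(length(sels$mcopa), 1L))
})
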