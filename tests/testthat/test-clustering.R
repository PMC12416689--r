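test_that("feature-to-observation ratios reproduce published descriptors", {
  expect_equal(round(feature_obs_ratio(2000, 62), 2), 32.26)
  expect_equal(round(feature_obs_ratio(12627, 20), 2), 631.35)
  expect_equal(round(feature_obs_ratio(7070, 72), 2), 98.19)
  expect_error(feature_obs_ratio(100, 0), "positive")
})

test_that("cluster search range follows the ratio-driven divisor rule", {
  r <- cluster_search_range(32.26)
  expect_identical(c(r$divisor, r$min_clusters, r$max_clusters), c(10L, 2L, 3L))
  r <- cluster_search_range(500)
  expect_identical(c(r$divisor, r$max_clusters), c(40L, 12L))
  r <- cluster_search_range(631.35)
  expect_identical(c(r$divisor, r$max_clusters), c(60L, 10L))
  # tiny ratios clamp the maximum up to the fixed minimum of 2
  r <- cluster_search_range(12)
  expect_identical(c(r$min_clusters, r$max_clusters), c(2L, 2L))
})

test_that("correlation embedding handles perfect, negated, and constant features", {
  x <- cbind(a = 1:10, b = 1:10, c = -(1:10), d = rep(3, 10))
  emb <- feature_embedding(x)
  expect_equal(emb["a", "b"], 1)
  expect_equal(emb["a", "c"], -1)
  expect_equal(unname(emb["d", c("a", "b", "c")]), c(0, 0, 0))
  expect_true(isSymmetric(emb))
  expect_error(feature_embedding(x[1, , drop = FALSE]), "observations")
})

test_that("independent feature pairs produce a block-diagonal correlation pattern", {
  stream <- rng_stream(21)
  n <- 500
  f1 <- stream_rnorm(stream, n)
  f2 <- stream_rnorm(stream, n)
  x <- cbind(f1, f1 + 0.01 * stream_rnorm(stream, n),
             f2, f2 + 0.01 * stream_rnorm(stream, n))
  emb <- feature_embedding(x)
  expect_gt(emb[1, 2], 0.99)
  expect_gt(emb[3, 4], 0.99)
  expect_lt(abs(emb[1, 3]), 0.15)
  expect_lt(abs(emb[2, 4]), 0.15)
})

test_that("partition scores match hand computation and the textbook oracles", {
  emb <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  sc <- score_partition(emb, c(1L, 1L, 2L, 2L), 2L)
  expect_equal(sc$db, 0.01)
  expect_equal(sc$silhouette, 0.98999975, tolerance = 1e-8)

  stream <- rng_stream(5)
  for (i in 1:25) {
    npts <- 5L + (i %% 4L)  # 5..8 points
    pts <- matrix(stream_rnorm(stream, npts * 2), ncol = 2)
    k <- 2L + (i %% 2L)
    labels <- rep(seq_len(k), length.out = npts)[
      order(stream_runif(stream, npts))]
    if (any(tabulate(labels, k) == 0L)) next
    sc <- score_partition(pts, labels, k)
    expect_equal(sc$db, db_oracle(pts, labels), tolerance = 1e-9)
    expect_equal(sc$silhouette, silhouette_oracle(pts, labels),
                 tolerance = 1e-9)
  }
})

test_that("degenerate partitions take the NaN pathway or error", {
  emb <- matrix(1, nrow = 4, ncol = 2)  # all points identical
  sc <- score_partition(emb, c(1L, 1L, 2L, 2L), 2L)
  expect_true(is.nan(sc$db))
  expect_true(is.nan(sc$silhouette))
  expect_error(score_partition(matrix(1:8, ncol = 2), rep(1L, 4), 2L),
               "empty cluster")
  expect_error(score_partition(matrix(1:8, ncol = 2), rep(1L, 4), 1L), ">= 2")
})

test_that("optimal-k selection finds planted groups and respects tie rules", {
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  pts <- block_points(centers, n_per = 8)
  rng <- cluster_search_range(45)  # range (2, 4)
  expect_identical(rng$max_clusters, 4L)
  model <- select_optimal_clusters(pts, rng)
  expect_identical(model$num_clusters, 3L)
  expect_true(all(model$score_table$combined_score >= 0 &
                    model$score_table$combined_score <= 1, na.rm = TRUE))
  # single-candidate range is forced
  rng2 <- cluster_search_range(25)
  expect_identical(select_optimal_clusters(pts, rng2)$num_clusters, 2L)
})

test_that("the chosen k is invariant to affine rescaling of one index", {
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6), c(6, 6))
  pts <- block_points(centers, n_per = 6, sd = 0.4)
  rng <- cluster_search_range(45)
  model <- select_optimal_clusters(pts, rng)
  st <- model$score_table
  # recompute the combined score after an affine map of the raw DB values;
  # min-max normalization must absorb it
  norm01 <- function(v) (v - min(v)) / (max(v) - min(v))
  rescaled <- 0.5 * norm01(3 + 7 * st$db) + 0.5 * (1 - norm01(st$silhouette))
  expect_identical(st$k[which.min(rescaled)], model$num_clusters)
})

test_that("feature cluster assignment partitions features and co-clusters duplicates", {
  lm <- label_copy_data(n = 30, d = 6)
  x <- lm$values
  x[, 4] <- x[, 2] + 1e-9  # duplicate correlation profile of feature 2
  model <- assign_feature_clusters(x, 2L)
  expect_identical(sort(unique(model$feature_clusters)), 1:2)
  expect_identical(model$feature_clusters[2], model$feature_clusters[4])
  # maximal cut: every feature its own cluster
  model_max <- assign_feature_clusters(x, 6L)
  expect_identical(sort(model_max$feature_clusters), 1:6)
  expect_error(assign_feature_clusters(x, 7L), "exceeds")
})

test_that("ward cut at k+1 splits exactly one cluster of the cut at k", {
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8))
  pts <- block_points(centers, n_per = 5, sd = 0.3)
  hc <- stats::hclust(stats::dist(pts), method = "ward.D2")
  for (k in 2:5) {
    a <- stats::cutree(hc, k)
    b <- stats::cutree(hc, k + 1)
    crossings <- table(a, b)
    split_counts <- rowSums(crossings > 0)
    expect_identical(sum(split_counts == 2L), 1L)
    expect_identical(sum(split_counts == 1L), as.integer(k - 1L))
  }
})

test_that("planted correlation blocks are reassembled up to relabeling", {
  skip_if_not_installed("mclust")
  out <- generate_synthetic(synthetic_spec(n_samples = 150, n_features = 120,
                                           n_blocks = 4, block_rho = 0.9,
                                           n_informative = 0, seed = 13))
  model <- assign_feature_clusters(out$data$values, 4L)
  ari <- mclust::adjustedRandIndex(model$feature_clusters, out$block_labels)
  expect_gte(ari, 0.9)
})
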