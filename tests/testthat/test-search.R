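test_that("non-selection rate decays linearly between its endpoints", {
  expect_equal(ur_value(0, 6000), 0.3)
  expect_equal(ur_value(6000, 6000), 0.001)
  expect_equal(ur_value(3000, 6000), 0.1505)
  fes <- seq(0, 6000, by = 200)
  urs <- vapply(fes, ur_value, numeric(1L), FEs_max = 6000)
  expect_true(all(diff(urs) < 0))
})

test_that("non-selection clears exactly min(UN, selected) distinct bits", {
  stream <- rng_stream(71)
  for (i in 1:1000) {
    d <- 10L + as.integer(stream_runif(stream) * 90)
    mask <- as.integer(stream_runif(stream, d) < 0.5)
    ur <- stream_runif(stream)
    out <- nonselection_operator(mask, ur, d, stream)
    un <- floor(ur * d + 0.5)
    expect_identical(sum(mask) - sum(out), as.integer(min(un, sum(mask))))
    expect_true(all(out <= mask))  # never turns bits on
  }
  # UN = 0 leaves the mask untouched
  mask <- c(1L, 0L, 1L)
  expect_identical(nonselection_operator(mask, 0.01, 3L, stream), mask)
})

test_that("selection operator rescues empty masks and leaves others alone", {
  stream <- rng_stream(73)
  reference <- c(1L, 0L, 1L, 0L, 0L)
  out <- selection_operator(rep(0L, 5), reference, 1L, stream)
  expect_identical(sum(out), 3L)  # reference restored + one flip
  expect_true(all(out >= reference))
  nonempty <- c(0L, 1L, 0L, 0L, 0L)
  expect_identical(selection_operator(nonempty, reference, 1L, stream),
                   nonempty)
  # degenerate: reference fully selected leaves nothing to flip
  full <- rep(1L, 4)
  expect_identical(selection_operator(rep(0L, 4), full, 1L, stream), full)
})

test_that("operator sequences never leave the incumbent empty", {
  stream <- rng_stream(79)
  d <- 50L
  mask <- as.integer(stream_runif(stream, d) < 0.5)
  mask <- selection_operator(mask, mask, 1L, stream)
  for (i in 1:10000) {
    proposal <- nonselection_operator(mask, stream_runif(stream), d, stream)
    proposal <- selection_operator(proposal, mask, 1L, stream)
    expect_gte(sum(proposal), 1L)
    mask <- proposal
  }
})

test_that("fitness is fold-mean 1-NN accuracy with expected extremes", {
  lm <- label_copy_data(n = 20, d = 5)
  folds <- stratified_kfold(lm$labels, 5, 1)
  perfect <- c(1L, 0L, 0L, 0L, 0L)  # the label-copy feature
  expect_equal(evaluate_fitness(perfect, lm$values, lm$labels, folds), 100)
  expect_error(evaluate_fitness(rep(0L, 5), lm$values, lm$labels, folds),
               "empty mask")
  twice <- evaluate_fitness(rep(1L, 5), lm$values, lm$labels, folds)
  expect_identical(evaluate_fitness(rep(1L, 5), lm$values, lm$labels, folds),
                   twice)
})

mini_fixture <- function(seed = 5) {
  generate_synthetic(synthetic_spec(n_samples = 40, n_features = 60,
                                    n_blocks = 6, n_informative = 3,
                                    effect_size = 2, imbalance_ratio = 1,
                                    seed = seed))
}

test_that("runs are reproducible bit-for-bit and trajectories never decrease", {
  synth <- mini_fixture()
  cfg <- search_config(FEs_max = 60, Run_max = 1, run_seeds = 301L)
  split <- make_split_plan(synth$data, 0.2, 5, 42)
  for (seed in 301:305) {
    r <- run_acg_sfe(cfg, synth$data, split, seed)
    expect_true(all(diff(r$fitness_trajectory) >= 0))
    expect_gte(r$n_selected, 1L)
  }
  r1 <- run_acg_sfe(cfg, synth$data, split, 301L)
  r2 <- run_acg_sfe(cfg, synth$data, split, 301L)
  expect_identical(r1$best_mask, r2$best_mask)
  expect_identical(r1$fitness_trajectory, r2$fitness_trajectory)
})

test_that("the per-cluster cap bounds every selected mask of a run", {
  synth <- mini_fixture(9)
  split <- make_split_plan(synth$data, 0.2, 5, 42)
  train <- synth$data$values[split$train_idx, ]
  cm <- fit_feature_clusters(train)
  cfg <- search_config(FEs_max = 80, Run_max = 1, run_seeds = 11L)
  r <- run_acg_sfe(cfg, synth$data, split, 11L, cluster_model = cm)
  # the tightest universal cap: base <= 3 and scaling factor <= 1.5
  cap <- ceiling(3 * 1.5)
  for (cl in seq_len(cm$num_clusters)) {
    expect_lte(sum(r$best_mask[cm$feature_clusters == cl]), cap)
  }
  expect_lte(r$n_selected, cm$num_clusters * cap)
})

test_that("plain SFE mode touches only operator-chosen positions", {
  synth <- mini_fixture(3)
  split <- make_split_plan(synth$data, 0.2, 5, 42)
  cfg <- search_config(FEs_max = 40, Run_max = 1, run_seeds = 21L,
                       mode = "sfe")
  r <- run_acg_sfe(cfg, synth$data, split, 21L)
  expect_true(all(diff(r$fitness_trajectory) >= 0))
  expect_gte(r$n_selected, 1L)
  # locality: replay the operator stream and confirm the same mask emerges
  r2 <- run_acg_sfe(cfg, synth$data, split, 21L)
  expect_identical(r$best_mask, r2$best_mask)
})

test_that("batches share folds across runs and are order-invariant", {
  synth <- mini_fixture(7)
  cfg <- search_config(FEs_max = 30, Run_max = 3,
                       run_seeds = c(41L, 42L, 43L))
  b <- run_batch(cfg, synth$data)
  expect_length(b$results, 3L)
  expect_identical(vapply(b$results, function(r) r$seed, integer(1L)),
                   c(41L, 42L, 43L))
  cfg_rev <- search_config(FEs_max = 30, Run_max = 3,
                           run_seeds = c(43L, 42L, 41L))
  b_rev <- run_batch(cfg_rev, synth$data)
  expect_identical(b_rev$results[[1L]]$best_mask, b$results[[3L]]$best_mask)
  expect_identical(b_rev$results[[3L]]$test_accuracy,
                   b$results[[1L]]$test_accuracy)
})
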