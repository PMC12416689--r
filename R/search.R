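# The adaptive cluster-guided SFE search: a single-agent hill climb over
# binary feature masks. Each iteration applies the non-selection operator
# (clear a decaying number of selected bits), rescues an emptied mask with
# the selection operator, optionally applies intra-cluster MI regularization,
# and greedily accepts the proposal when its cross-validated 1-NN accuracy is
# at least the incumbent's.

#' Search configuration
#'
#' Defaults are the study conditions: 6,000 function evaluations, 30
#' independent runs, non-selection rate decaying from 0.3 to 0.001, one
#' rescue flip (SN = 1), stratified 5-fold validation with a 1-NN fitness,
#' 10 MI bins, and partition seed 42.
#'
#' @param FEs_max Function-evaluation budget per run.
#' @param Run_max Number of independent runs in a batch.
#' @param UR_max,UR_min Initial and final non-selection rates, `0 < UR_min <
#'   UR_max < 1`.
#' @param SN Number of bits the selection operator flips on when rescuing an
#'   empty mask.
#' @param k_folds Stratified cross-validation folds inside the training set.
#' @param knn_k Neighbors for the KNN fitness classifier.
#' @param mi_bins Equal-width bins for the MI estimator.
#' @param split_seed Seed for the shared train/test and fold partitions.
#' @param test_fraction Held-out test proportion.
#' @param run_seeds Optional integer vector of per-run seeds (length
#'   `Run_max`); defaults to `10000 + 1:Run_max`.
#' @param regularize_scope `"all"` (rank every cluster member; the default,
#'   and the source of the method's run-to-run stability) or `"selected"`
#'   (regularize only the wrapper's current proposal).
#' @param mode `"acgsfe"` for the full method, `"sfe"` for the plain SFE
#'   baseline (no clustering, no regularization).
#' @return A list of class `search_config`.
#' @export
search_config <- function(FEs_max = 6000L, Run_max = 30L, UR_max = 0.3,
                          UR_min = 0.001, SN = 1L, k_folds = 5L, knn_k = 1L,
                          mi_bins = 10L, split_seed = 42L, test_fraction = 0.2,
                          run_seeds = NULL,
                          regularize_scope = c("all", "selected"),
                          mode = c("acgsfe", "sfe")) {
  stopifnot(UR_min > 0, UR_min < UR_max, UR_max < 1, SN >= 1L, FEs_max >= 1L,
            Run_max >= 1L, k_folds >= 2L, knn_k >= 1L, mi_bins >= 2L)
  if (is.null(run_seeds)) run_seeds <- 10000L + seq_len(Run_max)
  stopifnot(length(run_seeds) == Run_max)
  structure(
    list(FEs_max = as.integer(FEs_max), Run_max = as.integer(Run_max),
         UR_max = UR_max, UR_min = UR_min, SN = as.integer(SN),
         k_folds = as.integer(k_folds), knn_k = as.integer(knn_k),
         mi_bins = as.integer(mi_bins), split_seed = as.integer(split_seed),
         test_fraction = test_fraction, run_seeds = as.integer(run_seeds),
         regularize_scope = match.arg(regularize_scope),
         mode = match.arg(mode)),
    class = "search_config"
  )
}

#' Non-selection rate schedule
#'
#' Linear decay `(UR_max - UR_min) * ((FEs_max - FEs) / FEs_max) + UR_min`:
#' equals `UR_max` at `FEs = 0` and `UR_min` at `FEs = FEs_max`. The search
#' uses `ur_value(FEs - 1, ...)` for iteration `FEs`, so the first iteration
#' deselects at the full initial rate.
#'
#' @param FEs Evaluations spent so far, `0..FEs_max`.
#' @param FEs_max Evaluation budget.
#' @param UR_max,UR_min Schedule endpoints.
#' @return The non-selection rate at `FEs`.
#' @export
ur_value <- function(FEs, FEs_max, UR_max = 0.3, UR_min = 0.001) {
  stopifnot(FEs >= 0, FEs <= FEs_max)
  (UR_max - UR_min) * ((FEs_max - FEs) / FEs_max) + UR_min
}

# round half away from zero (the schedule only sees nonnegative values)
.round_half_up <- function(x) floor(x + 0.5)

#' Non-selection operator
#'
#' Clears `min(round(UR * Nvar), n_selected)` distinct selected bits chosen
#' uniformly. The input mask is not mutated; an all-zero result is possible
#' and is rescued downstream by [selection_operator()].
#'
#' @param mask Integer 0/1 vector.
#' @param UR Current non-selection rate.
#' @param Nvar Total number of features (not the selected count).
#' @param stream [rng_stream()] for the index draws.
#' @return The updated mask.
#' @export
nonselection_operator <- function(mask, UR, Nvar, stream) {
  un <- .round_half_up(UR * Nvar)
  selected <- which(mask == 1L)
  n_drop <- min(un, length(selected))
  if (n_drop > 0L) {
    mask[stream_sample(stream, selected, n_drop)] <- 0L
  }
  mask
}

#' Selection operator (rescue)
#'
#' Applied only when `mask` is empty: restores the pre-non-selection mask
#' `reference` and flips `SN` uniformly chosen non-selected bits on,
#' guaranteeing at least one selected feature. A non-empty mask is returned
#' unchanged, as is a reference with no non-selected bits left to flip.
#'
#' @param mask Candidate 0/1 mask (possibly empty).
#' @param reference The mask to restore from (the incumbent, i.e. the state
#'   before non-selection).
#' @param SN Number of bits to switch on.
#' @param stream [rng_stream()] for the index draws.
#' @return A mask with at least one selected bit whenever `reference` has a
#'   non-selected bit or is itself non-empty.
#' @export
selection_operator <- function(mask, reference, SN, stream) {
  if (any(mask == 1L)) return(mask)
  mask <- reference
  unselected <- which(mask == 0L)
  if (length(unselected) == 0L) return(mask)
  flip <- stream_sample(stream, unselected, min(SN, length(unselected)))
  mask[flip] <- 1L
  mask
}

.knn_predict <- function(train, test, cl, k) {
  as.character(class::knn(train = train, test = test, cl = factor(cl), k = k))
}

#' Cross-validated KNN fitness of a mask
#'
#' For each fold, a KNN classifier (Euclidean distance) is fit on the fold's
#' training rows restricted to the selected features and scored on the
#' fold's validation rows; the fitness is the mean fold accuracy as a
#' percentage.
#'
#' @param mask Integer 0/1 vector with at least one selected bit.
#' @param train_values Training matrix (samples x features).
#' @param labels Binary labels over the training rows.
#' @param folds A `split_plan` whose `fold_train_idx` / `fold_test_idx`
#'   index rows of `train_values`.
#' @param knn_k Number of neighbors (1 reproduces the study conditions).
#' @return Mean validation accuracy in percent.
#' @export
evaluate_fitness <- function(mask, train_values, labels, folds, knn_k = 1L) {
  selected <- which(mask == 1L)
  if (length(selected) == 0L) stop("cannot evaluate an empty mask")
  acc <- vapply(seq_along(folds$fold_test_idx), function(f) {
    tr <- folds$fold_train_idx[[f]]
    va <- folds$fold_test_idx[[f]]
    pred <- .knn_predict(train_values[tr, selected, drop = FALSE],
                         train_values[va, selected, drop = FALSE],
                         labels[tr], knn_k)
    mean(pred == as.character(labels[va]))
  }, numeric(1L))
  mean(acc) * 100
}

#' Run one adaptive cluster-guided SFE search
#'
#' Executes the full single-agent loop for one run: random initial mask
#' (each bit an independent fair coin), then `FEs_max` iterations of
#' non-selection (rate from [ur_value()]), empty-mask rescue, adaptive
#' MI-based intra-cluster regularization (skipped in `"sfe"` mode), fitness
#' evaluation, and greedy acceptance (ties accepted). Afterwards the best
#' mask is refit on the whole training partition and scored once on the
#' held-out test set. Two RNG streams are derived from `run_seed` —
#' one for the operators and initialization, one for the regularization
#' scaling draws — so disabling regularization does not perturb the
#' operator draws.
#'
#' @param config A [search_config()].
#' @param data A [labeled_matrix()].
#' @param split A full `split_plan` from [make_split_plan()].
#' @param run_seed Integer seed for this run's streams.
#' @param cluster_model Optional precomputed `cluster_model` (computed from
#'   the training partition when `NULL` and mode is `"acgsfe"`).
#' @param mi_scores Optional precomputed MI vector for the training
#'   partition.
#' @return A list of class `run_result`: `best_mask`, `fitness_trajectory`
#'   (best validation accuracy after each evaluation, non-decreasing),
#'   `n_selected`, `train_accuracy` (resubstitution), `test_accuracy`,
#'   `f_measure`, `confusion` (test-set counts), `seed`, `mode`.
#' @export
run_acg_sfe <- function(config, data, split, run_seed,
                        cluster_model = NULL, mi_scores = NULL) {
  stopifnot(inherits(config, "search_config"), inherits(data, "labeled_matrix"),
            inherits(split, "split_plan"))
  train_values <- data$values[split$train_idx, , drop = FALSE]
  y_train <- data$labels[split$train_idx]
  d <- ncol(train_values)
  use_reg <- config$mode == "acgsfe"
  if (use_reg && is.null(cluster_model)) {
    cluster_model <- fit_feature_clusters(train_values)
  }
  if (use_reg && is.null(mi_scores)) {
    mi_scores <- compute_mi_scores(train_values, y_train, config$mi_bins)
  }
  search_stream <- rng_stream(run_seed)
  reg_stream <- rng_stream(run_seed + 1000003L)

  mask <- as.integer(stream_runif(search_stream, d) < 0.5)
  mask <- selection_operator(mask, mask, config$SN, search_stream)
  fit_x <- evaluate_fitness(mask, train_values, y_train, split, config$knn_k)

  trajectory <- numeric(config$FEs_max)
  for (fes in seq_len(config$FEs_max)) {
    proposal <- mask
    ur <- ur_value(fes - 1L, config$FEs_max, config$UR_max, config$UR_min)
    proposal <- nonselection_operator(proposal, ur, d, search_stream)
    proposal <- selection_operator(proposal, mask, config$SN, search_stream)
    if (use_reg) {
      base <- adaptive_base_limit(fes, config$FEs_max)
      proposal <- apply_regularization(proposal, cluster_model, base,
                                       fes / config$FEs_max, reg_stream,
                                       mi_scores = mi_scores,
                                       scope = config$regularize_scope)
      proposal <- selection_operator(proposal, mask, config$SN, search_stream)
    }
    fit_new <- evaluate_fitness(proposal, train_values, y_train, split,
                                config$knn_k)
    if (fit_new >= fit_x) {
      mask <- proposal
      fit_x <- fit_new
    }
    trajectory[fes] <- fit_x
  }

  selected <- which(mask == 1L)
  test_values <- data$values[split$test_idx, , drop = FALSE]
  y_test <- data$labels[split$test_idx]
  pred_test <- .knn_predict(train_values[, selected, drop = FALSE],
                            test_values[, selected, drop = FALSE],
                            y_train, config$knn_k)
  pred_train <- .knn_predict(train_values[, selected, drop = FALSE],
                             train_values[, selected, drop = FALSE],
                             y_train, config$knn_k)
  positive <- minority_class(data$labels)
  conf <- confusion_counts(y_test, as.integer(pred_test), positive = positive)
  structure(
    list(best_mask = mask,
         fitness_trajectory = trajectory,
         n_selected = length(selected),
         train_accuracy = mean(as.integer(pred_train) == y_train) * 100,
         test_accuracy = accuracy(conf),
         f_measure = f_measure(conf),
         confusion = conf,
         seed = as.integer(run_seed),
         mode = config$mode),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result> mode ", x$mode, ", seed ", x$seed, ": ",
      x$n_selected, " features, test accuracy ",
      formatC(x$test_accuracy, format = "f", digits = 2), "%, F-measure ",
      formatC(x$f_measure, format = "f", digits = 2), "%\n", sep = "")
  invisible(x)
}

#' Run a batch of independent searches
#'
#' All runs share the seed-42-style partition plan (holdout plus folds) and
#' the once-per-dataset clustering and MI scores; each run draws from its
#' own seed.
#'
#' @param config A [search_config()].
#' @param data A [labeled_matrix()].
#' @param split Optional precomputed `split_plan`; built from the config
#'   when `NULL`.
#' @return A list of class `run_batch` with `results` (list of
#'   `run_result`), `split`, `cluster_model`, and `config`.
#' @export
run_batch <- function(config, data, split = NULL) {
  stopifnot(inherits(config, "search_config"), inherits(data, "labeled_matrix"))
  if (is.null(split)) {
    split <- make_split_plan(data, config$test_fraction, config$k_folds,
                             config$split_seed)
  }
  train_values <- data$values[split$train_idx, , drop = FALSE]
  y_train <- data$labels[split$train_idx]
  cluster_model <- NULL
  mi_scores <- NULL
  if (config$mode == "acgsfe") {
    cluster_model <- fit_feature_clusters(train_values)
    mi_scores <- compute_mi_scores(train_values, y_train, config$mi_bins)
  }
  results <- lapply(config$run_seeds, function(s) {
    run_acg_sfe(config, data, split, s, cluster_model, mi_scores)
  })
  structure(list(results = results, split = split,
                 cluster_model = cluster_model, config = config),
            class = "run_batch")
}
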