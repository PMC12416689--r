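# Deterministic stratified train/test holdout and k-fold partitions. One
# integer seed drives all shuffling through a dedicated RNG stream, kept
# separate from the search's streams so the partitions are identical across
# search runs.

#' Stratified train/test holdout split
#'
#' Per-class test counts are `round(class_count * test_fraction)`
#' (round-half-to-even); if their sum misses the global target
#' `round(n * test_fraction)` the largest class is adjusted by the difference.
#' Which samples land in the test set is decided by a seeded shuffle within
#' each class, so the split is identical for identical
#' `(labels, test_fraction, seed)`.
#'
#' @param data A [labeled_matrix()], or an integer 0/1 label vector.
#' @param test_fraction Proportion of samples held out, in (0, 1).
#' @param seed Integer seed for the split stream.
#' @return An object of class `split_plan` with `train_idx`, `test_idx`
#'   (1-based sample indices), `seed`, and empty fold slots.
#' @export
stratified_holdout <- function(data, test_fraction, seed) {
  labels <- if (inherits(data, "labeled_matrix")) data$labels else as.integer(data)
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- length(labels)
  classes <- sort(unique(labels))
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1L))
  target_total <- round(n * test_fraction)
  test_counts <- round(counts * test_fraction)
  delta <- target_total - sum(test_counts)
  if (delta != 0L) {
    big <- which.max(counts)
    test_counts[big] <- test_counts[big] + delta
  }
  if (any(test_counts < 1L) || any(test_counts >= counts)) {
    stop("class too small to stratify at test_fraction = ", test_fraction)
  }
  stream <- rng_stream(seed)
  test_idx <- integer(0L)
  for (i in seq_along(classes)) {
    members <- which(labels == classes[i])
    test_idx <- c(test_idx, stream_sample(stream, members, test_counts[i]))
  }
  test_idx <- sort(test_idx)
  structure(
    list(train_idx = setdiff(seq_len(n), test_idx), test_idx = test_idx,
         fold_train_idx = list(), fold_test_idx = list(),
         seed = as.integer(seed), k_folds = NA_integer_),
    class = "split_plan"
  )
}

#' Stratified k-fold partition
#'
#' Each class is shuffled under the seed and dealt round-robin into `k` folds,
#' so per-fold class proportions match the global proportions within one
#' sample per class. Indices are positions within the supplied label vector
#' (i.e. rows of the training partition when called on training labels).
#'
#' @param labels Integer 0/1 label vector (typically the training partition).
#' @param k Number of folds (>= 2); every class must have at least `k`
#'   samples.
#' @param seed Integer seed for the fold stream.
#' @return A `split_plan` whose `fold_train_idx`/`fold_test_idx` are lists of
#'   `k` disjoint index vectors partitioning `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k, seed) {
  labels <- as.integer(labels)
  stopifnot(k >= 2L)
  classes <- sort(unique(labels))
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1L))
  if (any(counts < k)) {
    stop("every class needs >= k samples (smallest class has ",
         min(counts), ", k = ", k, ")")
  }
  stream <- rng_stream(seed)
  fold_of <- integer(length(labels))
  for (cl in classes) {
    members <- which(labels == cl)
    members <- stream_sample(stream, members, length(members))
    fold_of[members] <- rep(seq_len(k), length.out = length(members))
  }
  fold_test <- lapply(seq_len(k), function(f) sort(which(fold_of == f)))
  fold_train <- lapply(fold_test, function(idx) setdiff(seq_along(labels), idx))
  structure(
    list(train_idx = seq_along(labels), test_idx = integer(0L),
         fold_train_idx = fold_train, fold_test_idx = fold_test,
         seed = as.integer(seed), k_folds = as.integer(k)),
    class = "split_plan"
  )
}

#' Full split plan: holdout plus cross-validation folds
#'
#' Combines [stratified_holdout()] and [stratified_kfold()] under one seed:
#' the 80/20-style holdout is drawn first, then the training partition is cut
#' into `k` stratified folds. Fold indices are positions within
#' `train_idx` (rows of the training matrix).
#'
#' @inheritParams stratified_holdout
#' @param k_folds Number of cross-validation folds inside the training set.
#' @return A complete `split_plan`.
#' @export
make_split_plan <- function(data, test_fraction = 0.2, k_folds = 5L, seed = 42L) {
  stopifnot(inherits(data, "labeled_matrix"))
  plan <- stratified_holdout(data, test_fraction, seed)
  folds <- stratified_kfold(data$labels[plan$train_idx], k_folds, seed)
  plan$fold_train_idx <- folds$fold_train_idx
  plan$fold_test_idx <- folds$fold_test_idx
  plan$k_folds <- as.integer(k_folds)
  plan
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> train ", length(x$train_idx), " / test ",
      length(x$test_idx), ", ", length(x$fold_test_idx),
      " folds, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Serialize a split plan to JSON
#'
#' Index lists are written 0-based for interoperability; [read_split_plan()]
#' restores 1-based indices. Serialization is byte-identical across repeated
#' calls with the same plan.
#'
#' @param plan A `split_plan`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  obj <- list(
    train_idx = as.integer(plan$train_idx) - 1L,
    test_idx = as.integer(plan$test_idx) - 1L,
    fold_train_idx = lapply(plan$fold_train_idx, function(i) as.integer(i) - 1L),
    fold_test_idx = lapply(plan$fold_test_idx, function(i) as.integer(i) - 1L),
    seed = plan$seed,
    k_folds = plan$k_folds
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a split plan written by [write_split_plan()]
#' @param path JSON path.
#' @return A `split_plan` with 1-based indices.
#' @export
read_split_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_idx <- function(x) if (length(x) == 0L) integer(0L) else as.integer(x) + 1L
  structure(
    list(train_idx = as_idx(obj$train_idx), test_idx = as_idx(obj$test_idx),
         fold_train_idx = lapply(obj$fold_train_idx, as_idx),
         fold_test_idx = lapply(obj$fold_test_idx, as_idx),
         seed = as.integer(obj$seed), k_folds = as.integer(obj$k_folds)),
    class = "split_plan"
  )
}
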