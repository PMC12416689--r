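# Evaluation metrics and multi-run aggregation: accuracy, F-measure,
# train-test RMSE (overfitting), feature reduction rate, Jaccard stability,
# and worst/best/mean/std summaries across independent runs.

#' Minority class of a binary label vector
#' @param labels Integer 0/1 vector.
#' @return The class code (0 or 1) with fewer samples; ties return 1.
#' @export
minority_class <- function(labels) {
  counts <- tabulate(as.integer(labels) + 1L, 2L)
  if (counts[2L] <= counts[1L]) 1L else 0L
}

#' Confusion counts for binary predictions
#'
#' @param truth,pred Integer 0/1 vectors of equal length.
#' @param positive Which class code counts as positive (default: 1). Use
#'   [minority_class()] to follow the minority-positive convention for
#'   imbalanced data.
#' @return A list of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred, positive = 1L) {
  stopifnot(length(truth) == length(pred))
  t_pos <- as.integer(truth) == positive
  p_pos <- as.integer(pred) == positive
  structure(
    list(tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
         fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos)),
    class = "confusion_counts"
  )
}

#' Classification accuracy (percent)
#' @param c A [confusion_counts()].
#' @return `100 * (tp + tn) / (tp + tn + fp + fn)`.
#' @export
accuracy <- function(c) {
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0L) stop("no evaluated samples")
  100 * (c$tp + c$tn) / total
}

#' F-measure (percent)
#'
#' Harmonic mean of precision and recall; returns 0 when `tp = 0` (the
#' degenerate-case convention).
#' @param c A [confusion_counts()].
#' @return F-measure in percent.
#' @export
f_measure <- function(c) {
  if (c$tp == 0L) return(0)
  p <- c$tp / (c$tp + c$fp)
  r <- c$tp / (c$tp + c$fn)
  100 * 2 * p * r / (p + r)
}

#' RMSE between paired train and test accuracies (percent)
#'
#' Quantifies overfitting; with a single pair this is `|train - test|`.
#' @param train_acc,test_acc Numeric percentage vectors of equal length.
#' @return `sqrt(mean((train - test)^2))`.
#' @export
rmse_train_test <- function(train_acc, test_acc) {
  if (length(train_acc) != length(test_acc)) stop("length mismatch")
  stopifnot(length(train_acc) >= 1L)
  sqrt(mean((train_acc - test_acc)^2))
}

#' Feature reduction rate (percent)
#' @param n_selected Number of selected features.
#' @param n_total Total number of features.
#' @return `100 * (1 - n_selected / n_total)`.
#' @export
frr <- function(n_selected, n_total) {
  stopifnot(n_total > 0, n_selected >= 0, n_selected <= n_total)
  100 * (1 - n_selected / n_total)
}

#' Jaccard similarity of two index sets (percent)
#'
#' `100 * |A intersect B| / |A union B|`. Two empty sets return 100 by
#' convention, with a warning, since two searches that both selected nothing
#' agree vacuously.
#' @param a,b Index vectors (selected feature indices).
#' @return Similarity in percent.
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) {
    warning("both sets empty; Jaccard defined as 100 by convention")
    return(100)
  }
  100 * length(intersect(a, b)) / length(union(a, b))
}

.mask_to_idx <- function(m) {
  if (inherits(m, "run_result")) m <- m$best_mask
  if (is.logical(m)) m <- as.integer(m)
  if (length(m) > 0L && all(m %in% c(0L, 1L)) && length(m) > max(1L, max(m))) {
    which(m == 1L)
  } else {
    as.integer(m)
  }
}

#' Stability of selected-feature sets across runs
#'
#' Pairwise Jaccard similarity over all unordered run pairs, per-feature
#' selection frequency, and the stable-feature set (features selected in
#' more than half of the runs).
#'
#' @param masks List of at least two masks: binary 0/1 vectors, index
#'   vectors, or `run_result` objects.
#' @return List with `worst`, `best`, `mean`, `std` (sample SD) of the
#'   pairwise Jaccard percentages, `pairwise` (the raw values),
#'   `selection_frequency` (named integer vector over features that were
#'   ever selected), and `stable_features` (indices with frequency >
#'   `n_runs / 2`).
#' @export
stability_summary <- function(masks) {
  if (length(masks) < 2L) stop("need at least 2 masks")
  sets <- lapply(masks, .mask_to_idx)
  r <- length(sets)
  pairs <- utils::combn(r, 2L)
  jac <- apply(pairs, 2L, function(p) jaccard_similarity(sets[[p[1L]]], sets[[p[2L]]]))
  freq_tab <- table(unlist(sets))
  freq <- as.integer(freq_tab)
  names(freq) <- names(freq_tab)
  stable <- sort(as.integer(names(freq_tab)[freq > r / 2]))
  list(worst = min(jac), best = max(jac), mean = mean(jac),
       std = if (length(jac) > 1L) stats::sd(jac) else 0,
       pairwise = jac, selection_frequency = freq, stable_features = stable)
}

.summarize <- function(x, larger_is_better) {
  list(worst = if (larger_is_better) min(x) else max(x),
       best = if (larger_is_better) max(x) else min(x),
       mean = mean(x),
       std = if (length(x) > 1L) stats::sd(x) else 0)
}

#' Aggregate a batch of runs into a metrics report
#'
#' Computes per-run metrics and their worst/best/mean/sample-SD summaries.
#' "Worst" is the minimum for accuracy, F-measure, FRR and Jaccard and the
#' maximum for RMSE and the number of selected features. The per-run RMSE is
#' `|train_accuracy - test_accuracy|`; Jaccard statistics pool all unordered
#' run pairs.
#'
#' @param results List of `run_result` objects (or a `run_batch`).
#' @param n_total_features Total feature count, for the FRR.
#' @return A list of class `metrics_report` with `per_run` (data frame) and
#'   `aggregate` (named list of summaries), plus the `stability` detail.
#' @export
aggregate_runs <- function(results, n_total_features) {
  if (inherits(results, "run_batch")) results <- results$results
  stopifnot(length(results) >= 1L)
  per_run <- data.frame(
    seed = vapply(results, function(r) r$seed, integer(1L)),
    test_accuracy = vapply(results, function(r) r$test_accuracy, numeric(1L)),
    f_measure = vapply(results, function(r) r$f_measure, numeric(1L)),
    train_accuracy = vapply(results, function(r) r$train_accuracy, numeric(1L)),
    n_selected = vapply(results, function(r) r$n_selected, integer(1L))
  )
  per_run$rmse <- abs(per_run$train_accuracy - per_run$test_accuracy)
  per_run$frr <- frr(per_run$n_selected, n_total_features)
  aggregate <- list(
    test_accuracy = .summarize(per_run$test_accuracy, TRUE),
    f_measure = .summarize(per_run$f_measure, TRUE),
    rmse = .summarize(per_run$rmse, FALSE),
    n_selected = .summarize(per_run$n_selected, FALSE),
    frr = .summarize(per_run$frr, TRUE)
  )
  stability <- NULL
  if (length(results) >= 2L) {
    stability <- stability_summary(lapply(results, function(r) r$best_mask))
    aggregate$jaccard <- stability[c("worst", "best", "mean", "std")]
  }
  structure(list(per_run = per_run, aggregate = aggregate,
                 stability = stability,
                 n_total_features = as.integer(n_total_features)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> ", nrow(x$per_run), " run(s), ",
      x$n_total_features, " features\n", sep = "")
  rows <- do.call(rbind, lapply(x$aggregate, function(s) {
    data.frame(worst = s$worst, best = s$best, mean = s$mean, std = s$std)
  }))
  rownames(rows) <- names(x$aggregate)
  print(round(rows, 2))
  invisible(x)
}
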