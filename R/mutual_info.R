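# Joint-histogram mutual information between a feature and the binary class
# label, in nats. Continuous features are discretized into equal-width bins
# over their observed range; labels are used as-is.

.bin_equal_width <- function(x, bins) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(rep(1L, length(x)))
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  codes <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(codes)
}

#' Mutual information from a joint histogram
#'
#' `x` is discretized into `bins` equal-width bins over `[min(x), max(x)]`
#' (a constant vector collapses to a single bin, giving 0); `y` is treated
#' as discrete. The estimate is
#' `sum over cells with p(x, y) > 0 of p(x, y) * ln(p(x, y) / (p(x) p(y)))`,
#' in nats. Zero-probability cells are skipped, so log(0) never arises.
#'
#' @param x Numeric feature vector.
#' @param y Discrete label vector of the same length.
#' @param bins Number of equal-width bins for `x` (>= 2).
#' @return Mutual information in nats (nonnegative up to rounding error).
#' @export
mutual_information <- function(x, y, bins = 10L) {
  if (length(x) != length(y)) {
    stop("length mismatch: x has ", length(x), ", y has ", length(y))
  }
  stopifnot(length(x) >= 2L, bins >= 2L)
  bx <- .bin_equal_width(as.numeric(x), bins)
  joint <- table(bx, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  expected <- outer(px, py)
  valid <- joint > 0
  sum(joint[valid] * log(joint[valid] / expected[valid]))
}

#' Mutual information of every feature with the labels
#'
#' @param train_values Numeric `n_obs x n_features` matrix.
#' @param y Binary label vector over the rows.
#' @param bins Equal-width bin count passed to [mutual_information()].
#' @return Numeric vector of per-feature MI values (nats). Computed once per
#'   training partition and cached by callers: labels and bins are fixed
#'   within a run, so scores never change across iterations.
#' @export
compute_mi_scores <- function(train_values, y, bins = 10L) {
  vapply(seq_len(ncol(train_values)),
         function(j) mutual_information(train_values[, j], y, bins),
         numeric(1L))
}

#' Rank features by mutual information with the labels
#'
#' Stable descending sort; ties break by ascending feature index.
#'
#' @param feature_indices Indices of the features to rank.
#' @param train_values Numeric matrix (samples x features), or `NULL` when
#'   `mi_scores` is supplied.
#' @param y Labels (ignored when `mi_scores` is supplied).
#' @param bins Bin count (ignored when `mi_scores` is supplied).
#' @param mi_scores Optional precomputed vector from [compute_mi_scores()].
#' @return `feature_indices` sorted by decreasing MI.
#' @export
rank_features_by_mi <- function(feature_indices, train_values = NULL, y = NULL,
                                bins = 10L, mi_scores = NULL) {
  feature_indices <- as.integer(feature_indices)
  if (length(feature_indices) == 0L) return(integer(0L))
  if (is.null(mi_scores)) {
    mi <- vapply(feature_indices,
                 function(j) mutual_information(train_values[, j], y, bins),
                 numeric(1L))
  } else {
    mi <- mi_scores[feature_indices]
  }
  feature_indices[order(-mi, feature_indices)]
}
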