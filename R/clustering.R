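# Dynamic hierarchical clustering of features. The number of clusters is
# searched over a range driven by the feature-to-observation ratio; every
# candidate k is scored by min-max-normalized Davies-Bouldin and Silhouette
# indices and the k minimizing the equally weighted combined score wins.
# Both the k search and the final assignment operate on the same embedding:
# rows of the feature Pearson correlation matrix, compared by Euclidean
# distance (the composition compatible with Ward's variance criterion).

#' Feature-to-observation ratio
#'
#' @param n_features,n_obs Positive integers.
#' @return The exact quotient `n_features / n_obs` (report rounded to two
#'   decimals where needed, e.g. 2000/62 prints as 32.26).
#' @export
feature_obs_ratio <- function(n_features, n_obs) {
  if (n_obs <= 0) stop("n_obs must be positive")
  n_features / n_obs
}

#' Cluster-count search range from the feature-to-observation ratio
#'
#' The divisor is `10 * ceiling(ratio / 100)` for ratios below 300 and ten
#' less for ratios of 300 or more; the maximum cluster count is
#' `floor(ratio / divisor)`, clamped up to 2 when the formula would fall
#' below the fixed minimum of 2.
#'
#' @param ratio Positive feature-to-observation ratio.
#' @return A list of class `cluster_search_range` with `min_clusters` (= 2),
#'   `max_clusters`, `divisor`, and `feature_obs_ratio`.
#' @export
cluster_search_range <- function(ratio) {
  stopifnot(ratio > 0)
  divisor <- if (ratio < 300) 10 * ceiling(ratio / 100) else 10 * ceiling(ratio / 100) - 10
  max_clusters <- floor(ratio / divisor)
  if (max_clusters < 2) max_clusters <- 2
  structure(
    list(min_clusters = 2L, max_clusters = as.integer(max_clusters),
         divisor = as.integer(divisor), feature_obs_ratio = ratio),
    class = "cluster_search_range"
  )
}

#' Feature embedding: the Pearson correlation matrix
#'
#' Each feature's row of the feature-feature correlation matrix is its
#' embedding point for clustering. Correlations that are undefined because a
#' feature has zero variance are set to 0 by convention, keeping the
#' embedding complete.
#'
#' @param train_values Numeric `n_obs x n_features` matrix (training
#'   partition).
#' @return Symmetric `n_features x n_features` correlation matrix.
#' @export
feature_embedding <- function(train_values) {
  train_values <- as.matrix(train_values)
  if (nrow(train_values) < 2L) stop("need >= 2 observations for correlations")
  cm <- suppressWarnings(stats::cor(train_values))
  cm[!is.finite(cm)] <- 0
  cm
}

# Davies-Bouldin index: mean over clusters of the worst (largest) ratio of
# summed centroid scatters to centroid separation. Lower is better.
.davies_bouldin <- function(embedding, labels, k) {
  centroids <- matrix(0, nrow = k, ncol = ncol(embedding))
  scatter <- numeric(k)
  for (i in seq_len(k)) {
    pts <- embedding[labels == i, , drop = FALSE]
    centroids[i, ] <- colMeans(pts)
    scatter[i] <- mean(sqrt(rowSums(sweep(pts, 2L, centroids[i, ])^2)))
  }
  sep <- as.matrix(stats::dist(centroids))
  r <- numeric(k)
  for (i in seq_len(k)) {
    ratio <- (scatter[i] + scatter[-i]) / sep[i, -i]
    r[i] <- max(ratio)
  }
  mean(r)
}

#' Score one clustering of the embedding
#'
#' Computes the Davies-Bouldin index (centroid scatter over centroid
#' separation, worst pair per cluster, averaged) and the mean Silhouette
#' width under Euclidean distance. Singleton clusters contribute silhouette
#' 0; if either index is uncomputable (e.g. coincident points) the value is
#' `NaN` rather than an error.
#'
#' @param embedding Numeric point matrix (points x dimensions).
#' @param labels Integer cluster labels in `1..k`; every cluster must be
#'   non-empty.
#' @param k Number of clusters (>= 2).
#' @return List with `db` and `silhouette`.
#' @export
score_partition <- function(embedding, labels, k) {
  embedding <- as.matrix(embedding)
  if (k < 2L) stop("k must be >= 2")
  counts <- tabulate(labels, nbins = k)
  if (any(counts == 0L)) stop("empty cluster in candidate labels")
  db <- tryCatch({
    v <- .davies_bouldin(embedding, labels, k)
    if (!is.finite(v)) NaN else v
  }, error = function(e) NaN)
  sil <- tryCatch({
    dmat <- stats::dist(embedding)
    if (max(dmat) == 0) stop("zero-diameter embedding")
    sw <- cluster::silhouette(labels, dmat)
    v <- mean(sw[, "sil_width"])
    if (!is.finite(v)) NaN else v
  }, error = function(e) NaN)
  list(db = db, silhouette = sil)
}

#' Select the optimal number of clusters
#'
#' Cuts one Ward linkage of the embedding at every candidate `k` in the
#' range, scores each cut with [score_partition()], min-max normalizes the
#' Davies-Bouldin and Silhouette values over the candidates with finite
#' scores, and picks the `k` minimizing
#' `0.5 * normalized_db + 0.5 * (1 - normalized_sil)`. Ties break to the
#' smallest `k`; if no candidate has finite scores the minimum of the range
#' is returned. When all candidates share an identical index value its
#' normalized value is defined as 0 (a constant term cannot discriminate).
#'
#' @param embedding Numeric point matrix (for feature clustering, the
#'   correlation matrix from [feature_embedding()]).
#' @param range A [cluster_search_range()].
#' @return A list of class `cluster_model` with `num_clusters`,
#'   `feature_clusters` (labels at the chosen `k`), and `score_table`
#'   (data frame of k, db, silhouette, normalized and combined scores).
#' @export
select_optimal_clusters <- function(embedding, range) {
  stopifnot(inherits(range, "cluster_search_range"))
  embedding <- as.matrix(embedding)
  ks <- seq.int(range$min_clusters, range$max_clusters)
  if (nrow(embedding) < range$max_clusters) {
    stop("fewer points (", nrow(embedding), ") than max_clusters (",
         range$max_clusters, ")")
  }
  hc <- stats::hclust(stats::dist(embedding), method = "ward.D2")
  cuts <- lapply(ks, function(k) as.integer(stats::cutree(hc, k = k)))
  db <- sil <- rep(NaN, length(ks))
  for (i in seq_along(ks)) {
    sc <- score_partition(embedding, cuts[[i]], ks[i])
    db[i] <- sc$db
    sil[i] <- sc$silhouette
  }
  norm01 <- function(v) {
    ok <- is.finite(v)
    out <- rep(NaN, length(v))
    if (!any(ok)) return(out)
    lo <- min(v[ok]); hi <- max(v[ok])
    out[ok] <- if (hi > lo) (v[ok] - lo) / (hi - lo) else 0
    out
  }
  ndb <- norm01(db)
  nsil <- norm01(sil)
  combined <- 0.5 * ndb + 0.5 * (1 - nsil)
  valid <- is.finite(combined)
  best <- if (any(valid)) ks[valid][which.min(combined[valid])] else range$min_clusters
  structure(
    list(num_clusters = as.integer(best),
         feature_clusters = cuts[[match(best, ks)]],
         score_table = data.frame(k = ks, db = db, silhouette = sil,
                                  normalized_db = ndb, normalized_sil = nsil,
                                  combined_score = combined)),
    class = "cluster_model"
  )
}

#' Assign features to a fixed number of clusters
#'
#' Ward linkage over rows of the feature correlation matrix (Euclidean
#' distance between correlation profiles), cut at `num_clusters`.
#'
#' @param train_values Numeric `n_obs x n_features` training matrix.
#' @param num_clusters Number of clusters, at most `n_features`.
#' @return A `cluster_model` (with `score_table = NULL`).
#' @export
assign_feature_clusters <- function(train_values, num_clusters) {
  d <- ncol(train_values)
  if (num_clusters > d) stop("num_clusters (", num_clusters,
                             ") exceeds n_features (", d, ")")
  emb <- feature_embedding(train_values)
  hc <- stats::hclust(stats::dist(emb), method = "ward.D2")
  structure(
    list(num_clusters = as.integer(num_clusters),
         feature_clusters = as.integer(stats::cutree(hc, k = num_clusters)),
         score_table = NULL),
    class = "cluster_model"
  )
}

#' Full feature-clustering stage
#'
#' Convenience wrapper running the whole stage on a training matrix: ratio,
#' search range, correlation embedding, optimal-k selection, and feature
#' assignment (one Ward linkage serves both the k search and the
#' assignment, since they act on the same embedding).
#'
#' @param train_values Numeric `n_obs x n_features` training matrix.
#' @return A `cluster_model` with the chosen `num_clusters`, per-feature
#'   labels, and the candidate score table.
#' @export
fit_feature_clusters <- function(train_values) {
  ratio <- feature_obs_ratio(ncol(train_values), nrow(train_values))
  rng <- cluster_search_range(ratio)
  emb <- feature_embedding(train_values)
  select_optimal_clusters(emb, rng)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> ", x$num_clusters, " clusters over ",
      length(x$feature_clusters), " features\n", sep = "")
  if (!is.null(x$score_table)) {
    print(x$score_table, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
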