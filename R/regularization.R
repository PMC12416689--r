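# Adaptive MI-based intra-cluster regularization. Per iteration, the
# candidate mask is rebuilt cluster by cluster: within each cluster only the
# top features by mutual information with the labels survive, and the cap on
# how many survive shrinks as the search spends its evaluation budget. The
# default candidate set is every member of the cluster ("all"), which makes
# the regularized mask a deterministic function of the MI ranking and the
# per-cluster cap draw -- the source of the method's near-perfect run-to-run
# stability; "selected" restricts candidates to the wrapper's current
# proposal, turning regularization into a pure pruning step.

#' Adaptive base feature limit per cluster
#'
#' `max(1, ceiling(((FEs_max - FEs) / FEs_max) * 3))`: allows up to three
#' features per cluster early in the search and tightens to one by the end.
#'
#' @param FEs Current function-evaluation count, `1..FEs_max`.
#' @param FEs_max Total evaluation budget.
#' @return Integer in `{1, 2, 3}`.
#' @export
adaptive_base_limit <- function(FEs, FEs_max) {
  stopifnot(FEs >= 1, FEs <= FEs_max)
  max(1L, as.integer(ceiling((FEs_max - FEs) / FEs_max * 3)))
}

#' Stochastic scaling factor for the per-cluster cap
#'
#' `1 + (1 - progress_factor) * 0.5 * u` with `u` uniform on \[0, 1\]: close
#' to 1.5 early (encouraging exploration), collapsing to exactly 1 when the
#' budget is spent.
#'
#' @param progress_factor Fraction of the budget used, `FEs / FEs_max`.
#' @param u A uniform draw in \[0, 1\].
#' @return Value in \[1, 1.5\].
#' @export
scaling_factor <- function(progress_factor, u) {
  stopifnot(progress_factor >= 0, progress_factor <= 1, u >= 0, u <= 1)
  1 + (1 - progress_factor) * 0.5 * u
}

#' Adaptive feature limit per cluster
#'
#' @param base Base limit from [adaptive_base_limit()].
#' @param sf Scaling factor from [scaling_factor()].
#' @return `ceiling(base * sf)`.
#' @export
adaptive_feature_limit <- function(base, sf) {
  stopifnot(base >= 1, sf >= 1, sf <= 1.5)
  as.integer(ceiling(base * sf))
}

#' Apply adaptive MI-based intra-cluster regularization to a mask
#'
#' The output mask starts from all zeros. For each cluster (in label order)
#' one fresh uniform draw from `stream` feeds the scaling factor; the
#' cluster's candidate features are ranked by mutual information with the
#' labels and the top `min(adaptive_feature_limit, n_candidates)` are
#' retained. With `scope = "all"` (the default) every feature of the cluster
#' is a candidate, so the regularized mask depends only on the MI ranking
#' and the cap draws — which is what gives the method its run-to-run
#' stability; `scope = "selected"` restricts candidates to the cluster's
#' features currently selected in `mask`, so regularization only ever prunes
#' the wrapper's proposal.
#'
#' @param mask Integer 0/1 vector over all features.
#' @param cluster_model A `cluster_model` (or plain integer label vector)
#'   covering all features.
#' @param base Base per-cluster limit from [adaptive_base_limit()].
#' @param progress_factor `FEs / FEs_max`.
#' @param stream [rng_stream()] supplying the per-cluster scaling draws.
#' @param train_values,y,bins Training matrix, labels and bin count used to
#'   compute MI scores when `mi_scores` is not supplied.
#' @param mi_scores Optional precomputed per-feature MI vector
#'   ([compute_mi_scores()]); supply it in loops to avoid recomputation.
#' @param scope `"selected"` or `"all"` (see above).
#' @return The regularized 0/1 mask.
#' @export
apply_regularization <- function(mask, cluster_model, base, progress_factor,
                                 stream, train_values = NULL, y = NULL,
                                 bins = 10L, mi_scores = NULL,
                                 scope = c("all", "selected")) {
  scope <- match.arg(scope)
  clusters <- if (inherits(cluster_model, "cluster_model")) {
    cluster_model$feature_clusters
  } else {
    as.integer(cluster_model)
  }
  if (length(clusters) != length(mask)) {
    stop("cluster labels do not cover the mask (", length(clusters),
         " vs ", length(mask), ")")
  }
  if (is.null(mi_scores)) {
    mi_scores <- compute_mi_scores(train_values, y, bins)
  }
  out <- integer(length(mask))
  for (cl in sort(unique(clusters))) {
    u <- stream_runif(stream, 1L)  # one draw per cluster, selected or not
    members <- which(clusters == cl)
    candidates <- if (scope == "selected") members[mask[members] == 1L] else members
    if (length(candidates) == 0L) next
    limit <- adaptive_feature_limit(base, scaling_factor(progress_factor, u))
    keep <- rank_features_by_mi(candidates, mi_scores = mi_scores)
    keep <- keep[seq_len(min(limit, length(keep)))]
    out[keep] <- 1L
  }
  out
}
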