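# Independent brute-force oracles used to validate the package's estimators.
# These are deliberately written from the textbook definitions with explicit
# loops, not by calling the code paths they check.

# mutual information by enumeration of the explicit joint distribution of two
# discrete vectors (nats)
mi_oracle <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      pxy <- sum(x == a & y == b) / n
      if (pxy > 0) {
        px <- sum(x == a) / n
        py <- sum(y == b) / n
        mi <- mi + pxy * log(pxy / (px * py))
      }
    }
  }
  mi
}

# Davies-Bouldin from the definition: per-cluster mean distance to centroid,
# worst pairwise (s_i + s_j) / d(c_i, c_j), averaged
db_oracle <- function(pts, labels) {
  pts <- as.matrix(pts)
  ids <- sort(unique(labels))
  cent <- lapply(ids, function(cl) colMeans(pts[labels == cl, , drop = FALSE]))
  scat <- vapply(seq_along(ids), function(i) {
    p <- pts[labels == ids[i], , drop = FALSE]
    mean(apply(p, 1L, function(row) sqrt(sum((row - cent[[i]])^2))))
  }, numeric(1L))
  worst <- vapply(seq_along(ids), function(i) {
    max(vapply(setdiff(seq_along(ids), i), function(j) {
      (scat[i] + scat[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
    }, numeric(1L)))
  }, numeric(1L))
  mean(worst)
}

# mean silhouette width from the definition; singletons contribute 0
silhouette_oracle <- function(pts, labels) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  dmat <- as.matrix(stats::dist(pts))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) next
    a <- mean(dmat[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(dmat[i, labels == cl])
    }, numeric(1L)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small well-separated feature-block fixture: n_per points per block around
# distinct centers in 2-D, for clustering tests
block_points <- function(centers, n_per, sd = 0.05, seed = 1) {
  stream <- rng_stream(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(centers[i, 1] + stream_rnorm(stream, n_per, sd = sd),
          centers[i, 2] + stream_rnorm(stream, n_per, sd = sd))
  }))
}

# tiny labeled dataset where one feature equals the label and the rest are
# seeded noise -- handy for fitness and ranking checks
label_copy_data <- function(n = 20, d = 5, seed = 3) {
  stream <- rng_stream(seed)
  y <- rep(c(0L, 1L), length.out = n)
  values <- matrix(stream_rnorm(stream, n * d), nrow = n)
  values[, 1L] <- y
  labeled_matrix(values, y)
}
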