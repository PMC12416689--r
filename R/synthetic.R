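# Synthetic high-dimensional binary-classification generator. Emulates the
# statistical shape of two-class microarray studies: features >> samples,
# block-correlated feature groups driven by shared latent factors, a small
# set of class-informative features, and balanced-to-moderately-imbalanced
# labels.

#' Specification for a synthetic expression dataset
#'
#' Defaults mirror a typical two-class microarray regime (on the order of a
#' Colon-cancer-sized study): 2,000 features on 62 samples with imbalance
#' ratio 1.82, twenty well-separated correlated feature blocks, and ten
#' informative features with a two-standard-deviation class shift. The
#' default `block_rho = 0.8` keeps the block structure dominant over the
#' correlation the class shift induces between informative features
#' (`e^2/4 / (1 + e^2/4)`, i.e. 0.5 at effect 2), so informative features
#' cluster with their blocks rather than with each other.
#'
#' @param n_samples Number of samples (rows).
#' @param n_features Number of features (columns).
#' @param n_blocks Number of correlated feature blocks; features are assigned
#'   to blocks in contiguous, near-equal groups.
#' @param block_rho Target pairwise Pearson correlation within a block, in
#'   \[0, 1). Achieved by the latent-factor construction
#'   `x = sqrt(rho) * f_block + sqrt(1 - rho) * eps` with standard normal
#'   factors, which gives correlation `rho` in expectation.
#' @param n_informative Number of class-informative features, distributed
#'   round-robin across blocks so that each cluster holds few informative
#'   members.
#' @param effect_size Standardized mean shift (in units of the feature
#'   standard deviation) added to informative features for class-1 samples.
#' @param imbalance_ratio Majority/minority class ratio, >= 1; class 1 is the
#'   minority class.
#' @param noise_sd Marginal standard deviation of every feature.
#' @param seed Integer seed; the generated matrix is a deterministic function
#'   of the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 62L, n_features = 2000L, n_blocks = 20L,
                           block_rho = 0.8, n_informative = 10L,
                           effect_size = 2.0, imbalance_ratio = 1.82,
                           noise_sd = 1.0, seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples),
               n_features = as.integer(n_features),
               n_blocks = as.integer(n_blocks),
               block_rho = block_rho,
               n_informative = as.integer(n_informative),
               effect_size = effect_size,
               imbalance_ratio = imbalance_ratio,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  stopifnot(spec$n_samples >= 4L, spec$n_features >= 1L,
            spec$n_blocks >= 1L, spec$n_blocks <= spec$n_features,
            spec$block_rho >= 0, spec$block_rho < 1,
            spec$n_informative >= 0L, spec$n_informative <= spec$n_features,
            spec$effect_size >= 0, spec$imbalance_ratio >= 1,
            spec$noise_sd > 0)
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", x$n_samples, " x ", x$n_features, ", ",
      x$n_blocks, " blocks (rho = ", x$block_rho, "), ",
      x$n_informative, " informative (effect ", x$effect_size, "), IR ",
      x$imbalance_ratio, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic block-correlated dataset
#'
#' Labels are assigned to match the imbalance ratio (minority count
#' `round(n_samples / (1 + IR))`, class 1 = minority) and shuffled under the
#' seed. Each feature is `noise_sd * (sqrt(rho) * f_b + sqrt(1 - rho) * eps)`
#' where `f_b` is the latent factor of its block; informative features
#' additionally receive `effect_size * noise_sd` for class-1 samples.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `data` (a [labeled_matrix()]), `block_labels`
#'   (integer block of each feature), `informative_idx` (indices of the
#'   informative features), and `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  d <- spec$n_features
  n_minor <- round(n / (1 + spec$imbalance_ratio))
  if (n_minor < 2L) {
    stop("infeasible imbalance ratio: minority class would have ",
         n_minor, " sample(s)")
  }
  stream <- rng_stream(spec$seed)

  y <- c(rep(0L, n - n_minor), rep(1L, n_minor))
  y <- stream_sample(stream, y, n)

  block_labels <- rep(seq_len(spec$n_blocks),
                      times = diff(round(seq(0, d, length.out = spec$n_blocks + 1))))

  factors <- matrix(stream_rnorm(stream, n * spec$n_blocks), nrow = n)
  eps <- matrix(stream_rnorm(stream, n * d), nrow = n)
  rho <- spec$block_rho
  values <- sqrt(rho) * factors[, block_labels, drop = FALSE] +
    sqrt(1 - rho) * eps
  values <- values * spec$noise_sd

  informative_idx <- integer(0L)
  if (spec$n_informative > 0L) {
    by_block <- split(seq_len(d), block_labels)
    taken <- integer(length(by_block))
    for (k in seq_len(spec$n_informative)) {
      b <- ((k - 1L) %% length(by_block)) + 1L
      # round-robin across blocks; skip exhausted blocks
      tries <- 0L
      while (taken[b] >= length(by_block[[b]]) && tries < length(by_block)) {
        b <- (b %% length(by_block)) + 1L
        tries <- tries + 1L
      }
      taken[b] <- taken[b] + 1L
      informative_idx <- c(informative_idx, by_block[[b]][taken[b]])
    }
    informative_idx <- sort(informative_idx)
    shift <- spec$effect_size * spec$noise_sd
    values[y == 1L, informative_idx] <- values[y == 1L, informative_idx] + shift
  }

  data <- labeled_matrix(values, y)
  list(data = data, block_labels = block_labels,
       informative_idx = informative_idx, spec = spec)
}

#' Write a synthetic dataset plus ground-truth sidecar
#'
#' Writes the matrix (with labels) via [write_labeled_matrix()] and a JSON
#' sidecar with the spec, the block label of every feature, and the indices
#' (0-based) of the informative features.
#'
#' @param synth Result of [generate_synthetic()].
#' @param path Output path for the matrix; the sidecar is
#'   `paste0(path, ".truth.json")`.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(synth, path) {
  write_labeled_matrix(synth$data, path)
  truth <- list(spec = unclass(synth$spec),
                block_labels = synth$block_labels,
                informative_idx = as.integer(synth$informative_idx) - 1L)
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
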