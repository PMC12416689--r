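# Named RNG streams. The search keeps three independent streams per run
# (operators, regularization scaling factor, initialization) so that turning a
# component on or off never perturbs the draws consumed by the others. Each
# stream owns a private .Random.seed state; draw helpers swap it in, draw, and
# swap the caller's global state back.

#' Create an independent random-number stream
#'
#' @param seed Integer seed initializing the stream (Mersenne-Twister).
#' @return An object of class `rng_stream` holding private generator state.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- new.env(parent = emptyenv())
  old <- .save_global_seed()
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = globalenv())
  .restore_global_seed(old)
  env$seed <- as.integer(seed)
  class(env) <- "rng_stream"
  env
}

.save_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

.with_stream <- function(stream, fn) {
  old <- .save_global_seed()
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    .restore_global_seed(old)
  })
  fn()
}

#' Uniform draws from a stream
#' @param stream An [rng_stream()].
#' @param n Number of draws.
#' @return Numeric vector of `n` draws in \[0, 1\].
#' @export
stream_runif <- function(stream, n = 1L) {
  .with_stream(stream, function() stats::runif(n))
}

#' Normal draws from a stream
#' @inheritParams stream_runif
#' @param mean,sd Normal parameters.
#' @export
stream_rnorm <- function(stream, n = 1L, mean = 0, sd = 1) {
  .with_stream(stream, function() stats::rnorm(n, mean = mean, sd = sd))
}

#' Sample without replacement from a stream
#'
#' Always treats `x` as the vector of values to sample from (no `sample()`
#' scalar surprise).
#' @inheritParams stream_runif
#' @param x Vector of candidate values.
#' @param size Number of values to draw.
#' @export
stream_sample <- function(stream, x, size) {
  stopifnot(size <= length(x))
  .with_stream(stream, function() x[sample.int(length(x), size)])
}

#' @export
print.rng_stream <- function(x, ...) {
  cat("<rng_stream> seed", x$seed, "\n")
  invisible(x)
}
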