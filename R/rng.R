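#' Seeded random-number streams
#'
#' Every stochastic behaviour in the engine (condition allocation, schedule
#' jitter, render-plan shuffles, simulated participant behaviour) draws from
#' a named stream derived from the master seed, so that adding modules or
#' participants never perturbs draws made for another purpose. Streams keep
#' a private copy of R's RNG state and never touch the global
#' \code{.Random.seed}.
#'
#' @param seed integer seed in \code{[0, 2^31 - 2]}.
#' @return An object of class \code{rng_stream}.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_global_seed(old))
    set.seed(as.integer(seed %% 2147483647))
    get(".Random.seed", envir = globalenv())
  })
  class(env) <- "rng_stream"
  env
}

restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Evaluate an expression under a stream's RNG state
#'
#' Swaps the stream's saved state into the global RNG, evaluates \code{expr},
#' captures the advanced state back into the stream, and restores the global
#' state that was in place before the call.
#'
#' @param stream an \code{rng_stream}.
#' @param expr expression performing RNG draws.
#' @export
with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit(restore_global_seed(old))
  out <- expr
  stream$state <- get(".Random.seed", envir = globalenv())
  out
}

#' @rdname with_stream
#' @param n,min,max as in \code{\link[stats]{runif}}.
#' @export
stream_runif <- function(stream, n = 1, min = 0, max = 1) {
  with_stream(stream, stats::runif(n, min, max))
}

#' @rdname with_stream
#' @param x,size,replace as in \code{\link{sample}}.
#' @export
stream_sample <- function(stream, x, size = length(x), replace = FALSE) {
  with_stream(stream, sample(x, size, replace = replace))
}

#' @rdname with_stream
#' @param rate exponential rate.
#' @export
stream_rexp <- function(stream, n = 1, rate = 1) {
  with_stream(stream, stats::rexp(n, rate))
}

#' @rdname with_stream
#' @param mean,sd normal parameters.
#' @export
stream_rnorm <- function(stream, n = 1, mean = 0, sd = 1) {
  with_stream(stream, stats::rnorm(n, mean, sd))
}

#' Derive a reproducible integer seed from string components
#'
#' A 31-bit polynomial hash over the concatenation of the components,
#' separated by \code{"|"}. Used to derive per-participant, per-purpose
#' stream seeds from \code{(study_id, participant index, purpose, master
#' seed)} so that stream identities are stable across runs and platforms.
#'
#' @param ... character or numeric components.
#' @return integer in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "|")
  bytes <- utf8ToInt(key)
  h <- 7
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}
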