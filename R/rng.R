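# Labelled, isolated random streams.
#
# The optimizers need reproducibility guarantees stronger than a single
# set.seed(): the hybrid runner must use the *same* BWO random draws whether
# or not IG refinement fires, so BWO and IG each consume a private stream
# derived from one master seed. A stream is an environment holding a saved
# .Random.seed; stream_do() swaps it in, evaluates, and swaps it back out,
# leaving the caller's RNG state untouched.

#' Derive a sub-seed from a master seed and a label
#'
#' Deterministically maps (seed, label) to an integer in [0, 2^31), so that
#' independent components (initialization, BWO operators, IG, CV folds,
#' per-run seeds) each get their own reproducible stream.
#'
#' @param seed integer master seed.
#' @param label character tag naming the stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}

#' Create a random stream
#'
#' @param seed integer seed for the stream.
#' @return an environment with the stream's saved RNG state.
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

#' Evaluate an expression under a stream's RNG state
#'
#' Installs the stream's state, evaluates `expr`, saves the advanced state
#' back into the stream and restores the caller's RNG state.
#'
#' @param stream an [rng_stream()].
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
stream_do <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# Run expr with a temporary seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  stream_do(rng_stream(seed), expr)
}
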