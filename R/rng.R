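## Lightweight named RNG streams so that the trial-type, delay and agent
## margins of a simulated session are reproducible independently of one
## another. Each stream owns a saved .Random.seed; draws swap it into the
## global environment, evaluate, and swap the previous state back.

#' Create an independent seeded random stream
#'
#' A stream is an environment holding a private \code{.Random.seed}. Child
#' streams derived from one root seed (see [childSeed()]) let the simulator
#' keep trial-type assignment, delay sampling and agent behavior on separate
#' reproducible margins: changing the agent cannot perturb the trial sequence.
#'
#' @param seed Integer seed.
#' @return An environment with a \code{state} binding, class
#'   \code{"rng_stream"}.
#' @examples
#' s <- rngStream(1)
#' withStream(s, runif(2))
#' @export
rngStream <- function(seed) {
  stream <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  stream$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(stream) <- "rng_stream"
  stream
}

#' Evaluate an expression under a stream's RNG state
#'
#' The stream's state advances; the global RNG state is untouched.
#'
#' @param stream An object from [rngStream()].
#' @param expr Expression using R's random number generators.
#' @return The value of \code{expr}.
#' @export
withStream <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
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

#' Derive a child seed from a root seed
#'
#' Deterministic integer mixing (Lehmer step modulo the Mersenne prime
#' 2^31 - 1) keeps every derived seed a valid 32-bit integer.
#'
#' @param seed Root integer seed.
#' @param k Child index (1 = trial type, 2 = delay, 3 = agent, ... by
#'   convention).
#' @return An integer seed.
#' @export
childSeed <- function(seed, k) {
  m <- 2147483647
  s <- (as.double(seed) %% m + m) %% m
  for (i in seq_len(k)) s <- (s * 48271 + 11) %% m
  as.integer(s)
}
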