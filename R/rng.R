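# Seedable RNG state owned by the simulation, kept out of the user's
# global random stream. All stochastic draws in a session (event
# scheduling, monologue, policy randomness, respondent generation) flow
# through these helpers so that (seed, action script) -> identical logs.

#' Create a Mersenne-Twister RNG state from an integer seed
#'
#' Returns the `.Random.seed` vector produced by `set.seed(seed)`,
#' without disturbing the caller's random stream.
#'
#' @param seed single finite number; coerced to integer.
#' @return an opaque RNG state vector usable with [with_rng()].
#' @export
rng_state <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    config_error("seed must be a single finite number, got %s",
                 deparse(substitute(seed)))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  get(".Random.seed", envir = globalenv(), inherits = FALSE)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate a drawing function under a stored RNG state
#'
#' @param state RNG state from [rng_state()].
#' @param f zero-argument function performing draws from the global RNG.
#' @return `list(value = f(), state = <advanced state>)`.
#' @export
with_rng <- function(state, f) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  assign(".Random.seed", state, envir = globalenv())
  value <- f()
  list(value = value,
       state = get(".Random.seed", envir = globalenv(), inherits = FALSE))
}

# draw through a sim object, returning list(sim, value)
sim_draw <- function(sim, f) {
  r <- with_rng(sim$rng, f)
  sim$rng <- r$state
  list(sim = sim, value = r$value)
}
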