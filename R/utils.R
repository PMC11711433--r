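# Seeded random-stream helpers. Every stochastic component draws from an
# isolated stream so that components compose deterministically regardless of
# call order elsewhere.

#' Create an isolated, seeded random stream
#'
#' Returns a generator object with `runif(n)`, `rnorm(n, sd)`, `rpois(n,
#' lambda)` and `sample_int(n)` (a permutation of `1:n`) methods. The stream
#' keeps its own state: draws are reproducible given the seed and unaffected
#' by other uses of R's RNG.
#'
#' @param seed integer seed.
#' @return a `seed_rng` object (list of closures).
#' @export
seed_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  draw <- function(fn) {
    force(fn)
    function(...) {
      prev <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        get(".Random.seed", globalenv())
      } else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- fn(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(prev)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", prev, globalenv())
      }
      out
    }
  }
  structure(list(
    runif = draw(function(n, min = 0, max = 1) stats::runif(n, min, max)),
    rnorm = draw(function(n, mean = 0, sd = 1) stats::rnorm(n, mean, sd)),
    rpois = draw(function(n, lambda) stats::rpois(n, lambda)),
    sample_int = draw(function(n) sample.int(n)),
    seed = as.integer(seed)
  ), class = "seed_rng")
}

# Derive a sub-seed from a base seed and an index; stays below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}
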