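# Seeded substreams: every stochastic operation takes a seed and runs in a
# keyed substream of it, so results are reproducible and independent of the
# order in which operations are invoked (and of how work is partitioned
# across workers).

#' Derive a substream seed from a master seed and an integer key
#'
#' A small multiplicative hash mapping (seed, key) pairs to 31-bit integers.
#' Distinct keys under the same master seed give effectively independent
#' Mersenne-Twister streams; the same (seed, key) always maps to the same
#' stream.
#'
#' @param seed Master seed (integer).
#' @param key Non-negative integer stream key.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, key = 0L) {
  # all intermediates stay below 2^53 so double arithmetic is exact
  s <- as.double(seed) %% 94906249
  k <- as.double(key) %% 94906249
  x <- (s * 22695477 + k + 1013904223) %% 2147483629
  x <- (x * 69069 + 1) %% 2147483629
  as.integer(x)
}

#' Evaluate an expression in a seeded RNG substream
#'
#' Saves and restores the caller's RNG state, so library code never
#' perturbs the global random stream.
#'
#' @param seed,key Passed to [substream_seed()].
#' @param expr Expression to evaluate.
#' @keywords internal
with_substream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, key))
  expr
}
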