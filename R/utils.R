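# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded internals never perturb user-level random streams.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# round half away from zero; base round() is half-to-even
round_half_up <- function(x) floor(x + 0.5)

# clip intensities into [0, 255]
clip255 <- function(x) pmin(255, pmax(0, x))

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# derive a stream of sub-seeds from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
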