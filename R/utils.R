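# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a base seed and a salt
#'
#' Linear-congruential mixing keeps derived seeds inside the 32-bit integer
#' range expected by [set.seed()].
#' @param seed base integer seed
#' @param salt integer stream/batch identifier
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, salt = 0L) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(salt) * 16807 + 1
  as.integer(s %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  Keeps generator functions pure in their
# seed without perturbing the session RNG.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# round-half-up to integers (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# clip numeric values into [lo, hi]
clip <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

stop_dc <- function(...) stop(..., call. = FALSE)
warn_dc <- function(...) warning(..., call. = FALSE)
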