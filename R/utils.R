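# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a local RNG state
#'
#' Seeds the RNG if `seed` is non-NULL and restores the caller's RNG state on
#' exit, so library functions do not disturb user-level random streams.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a stream of child seeds from a master seed
#'
#' @param seed master seed (integer) or NULL.
#' @param n number of child seeds.
#' @return integer vector of length `n`, all below 2^31.
#' @noRd
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_if_not <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == round(x) && x >= 1

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# round to the 1 ms presentation grid used for all event times
round_ms <- function(x) round(x, 3)
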