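#' @keywords internal
"_PACKAGE"

## NULL-coalescing helper used throughout for optional config fields.
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from a single integer seed. Individual
#' stages (per-class layout draws, crime sampling, each cross-validation
#' repeat, ...) use sub-seeds derived deterministically from the base seed and
#' a stage label, so any stage can be reproduced in isolation without
#' re-running the stages before it.
#'
#' The derivation is a polynomial rolling hash of the label characters and any
#' integer indices, reduced modulo 2^31 - 1 so the result is always a valid R
#' integer seed.
#'
#' @param seed base integer seed.
#' @param ... stage labels (character) and/or integer indices mixed in order.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (part in list(...)) {
    if (is.character(part)) {
      codes <- utf8ToInt(paste(part, collapse = "/"))
    } else {
      codes <- as.numeric(part)
    }
    for (cd in codes) {
      h <- (h * 131 + cd + 7) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

## Run an expression under a local RNG state seeded with `seed`; the caller's
## RNG state is untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_poicrime <- function(..., class = "poicrime_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

## Nearest-rank percentile on a sorted vector: smallest value with at least
## p*n observations at or below it.
nearest_rank <- function(x, p) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sort(x)[max(1L, ceiling(p * n))]
}
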