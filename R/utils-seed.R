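#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so callers never perturb user-level randomness.
#' A `NULL` seed runs the code against the current RNG stream.
#'
#' @param seed integer seed or `NULL`
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Fast data.frame construction for hot loops
#'
#' Bypasses `data.frame()`'s coercion machinery; all columns must already
#' be equal-length atomic vectors.
#' @keywords internal
quick_df <- function(...) {
  x <- list(...)
  structure(x, class = "data.frame",
            row.names = .set_row_names(length(x[[1]])))
}

#' Derive a stream-specific child seed
#'
#' Deterministically folds integer components into a parent seed so that
#' every mouse / day / trial / region gets an independent, reproducible
#' stream. All arithmetic stays below 2^53 so the result is exact, and the
#' returned seed is a valid 32-bit integer.
#'
#' @param seed parent seed (integer)
#' @param ... integer components (trial index, region index, ...)
#' @return integer seed in `[1, 2147483646]`
#' @keywords internal
derive_seed <- function(seed, ...) {
  x <- as.double(seed) %% 2147483647
  for (k in c(...)) {
    x <- ((x %% 94906265) * 22695477 + as.double(k) * 2654435 + 1) %% 2147483647
  }
  as.integer(x + 1)
}
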