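# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of their
#' parameters and seed, and never perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a component-specific substream seed from a global seed
#'
#' Each generator hashes its own name so adding a new generator never perturbs
#' the streams of existing ones. Result is kept below 2^31 - 1.
#' @noRd
fanout_seed <- function(seed, component) {
  ch <- utf8ToInt(component)
  h <- sum(ch * seq_along(ch)) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == floor(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
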