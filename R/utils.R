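# Internal utilities: seeded evaluation and seed fan-out.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals never
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a root seed
#'
#' One root seed is fanned out deterministically to the pipeline's stochastic
#' stages (splitting, weight initialisation, augmentation, bootstrap) so that
#' a single recorded integer reproduces a whole run. The derived seed stays
#' below 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param stream non-negative integer stream index.
#' @return an integer seed.
#' @export
#' @examples
#' fanSeed(1, 0)
#' fanSeed(1, 3)
fanSeed <- function(seed, stream = 0L) {
  s <- (as.double(seed) %% 65011) * 33013 + as.double(stream) * 9973 + 17
  as.integer(s %% 2147483647)
}

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

# locale-stable lexicographic sort for paths
sortLex <- function(x) sort(x, method = "radix")
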