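## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library calls never perturb the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## Numerically standard logistic; inputs are pre-activation sums of
## Xavier-scaled terms, so no special overflow guard is required beyond
## exp()'s own saturation (which yields exactly 0 or 1 at +/-Inf).
sigmoid <- function(x) 1 / (1 + exp(-x))

## Stop with a formatted message, no call echo.
fail <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

## Locale-independent lexicographic sort (radix method uses C ordering),
## so label spaces are reproducible across machines.
sort_c <- function(x) sort(x, method = "radix")
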