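## Internal helpers: seeded evaluation and deterministic substreams.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return value of `code`
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific seed from a master seed
#'
#' Stable hashing keeps per-stage randomness independent of stage order, so
#' adding a stage does not reshuffle earlier streams. Result is < 2^31.
#'
#' @param seed master integer seed
#' @param label stage label
#' @return integer seed
#' @export
#' @examples
#' substream_seed(42, "simulate")
substream_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 1000003L
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483563)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

## round a numeric to integer days, half away from zero (deterministic)
as_day <- function(x) as.integer(floor(x + 0.5))
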