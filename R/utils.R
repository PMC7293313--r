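## Internal helpers: seeded RNG scoping and small numeric utilities.

#' Derive a component seed from a master seed
#'
#' Each pipeline stage draws from its own RNG stream so that re-running a
#' single stage in isolation reproduces exactly what the full pipeline did.
#' The derived seed is a deterministic function of the master seed and a
#' component label, kept within 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param label character label of the component stream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483399) + 1L
}

## Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## assert helper with sprintf-style message
check_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
  invisible(TRUE)
}

## sample variance that returns 0 (not NA) for length-1 input
var0 <- function(x) if (length(x) < 2L) 0 else stats::var(x)
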