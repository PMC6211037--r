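## Seed plumbing: every stochastic operation takes an integer seed and leaves
## the caller's RNG state untouched.  Substreams are derived deterministically
## from a root seed plus a string key so that independent stages of a pipeline
## never share a stream.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the RNG, evaluates `expr`, and
#' restores the previous state, so seeded operations are referentially
#' transparent.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_rng_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible substream seed
#'
#' Combines a root seed with a string key (and optional index) into a new
#' seed below 2^31, so each stage of a pipeline draws from its own stream.
#'
#' @param seed Root integer seed.
#' @param key Character label naming the substream.
#' @param index Optional integer (e.g. a group counter).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1L, "synth", 3L)
derive_seed <- function(seed, key, index = 0L) {
  stopifnot(is.character(key), length(key) == 1L)
  m <- 2147483647  # 2^31 - 1, keep everything in exact double arithmetic
  h <- 5381
  for (b in utf8ToInt(key)) h <- (h * 33 + b) %% m
  s <- (as.numeric(seed) %% m + 1) * 48271 %% m
  as.integer((s + h * 7919 + as.numeric(index) * 104729) %% m)
}
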