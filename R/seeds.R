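#' Derive a child seed from a base seed and a key
#'
#' Deterministically folds a base seed together with an arbitrary sequence of
#' string/numeric keys into a single integer seed in `[1, 2^31 - 1]`.
#' Replicates of a simulation study each get their own child seed keyed on
#' the replicate index (and any scenario labels), so each replicate is
#' individually reproducible and independent of execution order.
#'
#' The folding is a multiplicative-congruential hash modulo the Mersenne
#' prime `2^31 - 1`; all arithmetic stays below 2^53 so the result is exact
#' in double precision on every platform.
#'
#' @param base_seed Integer base seed for the whole study.
#' @param ... Keys (character or numeric scalars/vectors) identifying the
#'   stream, e.g. `child_seed(42, "obs", "early", 0.15, rep = 7)`.
#' @return A single integer seed.
#' @examples
#' child_seed(42, "obs", "steady", 0.15, 1)
#' @export
child_seed <- function(base_seed, ...) {
  keys <- unlist(lapply(list(...), function(k) {
    if (is.character(k)) {
      unlist(lapply(k, utf8ToInt))
    } else {
      as.numeric(k)
    }
  }), use.names = FALSE)
  m <- 2147483647
  h <- abs(as.numeric(base_seed)) %% m
  for (k in c(length(keys), keys)) {
    # scale fractional keys up so e.g. 0.15 and 0.2 hash differently
    h <- (h * 48271 + abs(k) * 7919 + (k < 0) * 104729 + 1) %% m
  }
  as.integer(h %% (m - 1L)) + 1L
}

# Run code under a temporary RNG seed without disturbing the caller's RNG
# state; a NULL seed uses (and advances) the current stream.
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}
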