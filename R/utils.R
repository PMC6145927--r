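# Internal helpers shared across modules.

# Run code under a fixed seed without touching the caller's RNG stream.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream-specific child seed from a master seed (kept < 2^31).
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

assertScalarProb <- function(x, name, openTop = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      (if (openTop) x >= 1 else x > 1))
    stop(sprintf("%s must be a single number in [0, %s", name,
                 if (openTop) "1)" else "1]"), call. = FALSE)
  invisible(x)
}
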