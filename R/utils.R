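# Deterministic per-stage seed derivation from one global seed.
# Simple multiplicative hash kept below 2^31 so set.seed() accepts it.
#' Derive a stage seed from a global seed
#'
#' @param seed global integer seed.
#' @param k stage index (any small integer).
#' @return An integer in [1, 2^31 - 2], deterministic in (seed, k).
#' @export
deriveSeed <- function(seed, k) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- (as.numeric(seed) %% m) * 48271 %% m
  s <- (s + as.numeric(k) * 16807) %% m
  s <- (s * 69621) %% m
  as.integer(if (s == 0) 1 else s)
}

# warn-once style messaging helper used by filters
dropMessage <- function(step, before, after) {
  message(sprintf("%s: %d -> %d features/samples retained", step, before, after))
}
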