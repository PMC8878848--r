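#' Derive a stream seed from the run seed
#'
#' Stable integer hash of (seed, purpose, cycle, replica), used so that every
#' random stream in a run (initial arrangement, per-replica velocity draws,
#' per-segment noise) gets its own reproducible seed regardless of execution
#' order. The result is always in [1, 2^31 - 2].
#'
#' @param seed run-level integer seed.
#' @param purpose short string naming the stream.
#' @param cycle,replica integer indices (0 when not applicable).
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, purpose, cycle = 0L, replica = 0L) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(purpose)) h <- (h * 131 + b) %% m
  h <- (h * 7919 + as.numeric(cycle) * 104729 + as.numeric(replica) * 131071) %% m
  as.integer(h %% (m - 1)) + 1L
}

format_sig9 <- function(x) {
  # fixed 9-significant-digit text for CSV output
  formatC(x, digits = 9, format = "g")
}
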