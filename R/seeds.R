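#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one root seed. Stages and
#' per-unit draws (one melody, one participant, one bootstrap replicate)
#' use named sub-streams derived deterministically from that root, so a
#' stage can be re-run in isolation and a set is invariant to the order
#' in which its elements are generated.
#'
#' The derivation is a small integer hash (splitmix-style multiply/xor on
#' doubles, reduced mod 2^31 - 1) of the root seed and a tag; it is not
#' cryptographic, only a stable well-spread map to valid R seeds.
#'
#' @param seed integer root seed.
#' @param tag character scalar naming the sub-stream (e.g. "melody7").
#' @return an integer in [1, 2^31 - 2] usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "melodies_sing")
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag), length(tag) == 1)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps everything in exact doubles
  h <- (abs(seed) %% m)
  for (k in utf8ToInt(tag)) {
    h <- (h * 31 + k) %% m
    # xor-free avalanche that stays exact in double arithmetic
    h <- (h * 48271) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
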