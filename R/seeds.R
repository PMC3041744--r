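#' Derive a deterministic child seed for a named pipeline stage
#'
#' Stages of a simulation or pipeline run draw their randomness from seeds
#' derived from one global seed plus a stage label, so each stage is
#' independently reproducible. The derivation is an FNV-1a style hash of the
#' label folded into the seed, reduced modulo 2^31 - 1 so the result is a
#' valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage label (e.g. `"breeds"`, `"cross"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' childSeed(1, "breeds")
#' @export
childSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 2166136261
  for (ch in utf8ToInt(stage)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  as.integer((abs(seed) + h) %% 2147483647)
}
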