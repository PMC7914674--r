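#' Derive a named substream seed from a master seed
#'
#' Every stage of a pipeline (simulation, splitting, training, prediction)
#' draws its own seed deterministically from one master seed and a stage
#' name, so stages are independently reproducible and re-ordering one stage
#' does not disturb another.
#'
#' @param seed Master seed (integer).
#' @param key Stage name (character) or an integer stream index.
#' @return An integer seed in 0..2^31-2.
#' @export
substream_seed <- function(seed, key) {
  if (is.character(key)) {
    v <- utf8ToInt(key)
    key <- sum(v * seq_along(v)) %% 2147483647
  }
  m <- 2147483647  # 2^31 - 1
  s <- (as.numeric(seed) %% m) * 48271 %% m
  as.integer((s + (as.numeric(key) %% m) * 16807) %% m)
}
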