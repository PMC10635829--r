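#' Derive a reproducible substream seed from a master seed
#'
#' All stochastic steps in the package draw their randomness from one master
#' seed via named substreams, so that e.g. the genome sequence is identical
#' across runs that only change the read-sampling stream.  The derivation is
#' a small deterministic integer hash of the stream name folded into the
#' master seed; the result always fits in a 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param stream character scalar naming the substream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(1L, "genome")
substream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  h <- abs(as.numeric(master)) %% 2147483647
  for (v in utf8ToInt(stream)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression under a fixed RNG seed, restoring state afterwards
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
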