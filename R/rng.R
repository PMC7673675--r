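#' Derive a reproducible substream seed
#'
#' All generators in the package draw their randomness from a master seed
#' plus a per-operation label, so adding a generator call to a script does
#' not shift the random stream of any other call.  The label is hashed to
#' an integer with a small polynomial rolling hash and folded into the
#' master seed.
#'
#' @param seed master seed (single integer).
#' @param label character scalar naming the substream (e.g. `"slips"`).
#' @return an integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @examples
#' substream_seed(1, "slips")
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (cc in utf8ToInt(label)) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

# Run `expr` under a substream seed without disturbing the caller's RNG.
with_substream <- function(seed, label, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(substream_seed(seed, label))
  expr
}
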