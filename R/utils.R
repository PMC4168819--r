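#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; genomic region sizes here follow
#' the conventional half-up rule (14472571 bp -> 14.5 Mb).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## stop() with a condition class so callers can catch specific failures
.err <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "rohdel_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

.checkSeed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    .err("rohdel_bad_seed", "seed must be a single integer")
  as.integer(seed)
}

## derive a stream-specific child seed so independent generators fed from one
## user seed do not reuse the same RNG stream; kept below 2^31
.childSeed <- function(seed, stream) {
  (as.integer(seed) * 48271 + stream * 1009) %% 2147483647L
}
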