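#' @keywords internal
"_PACKAGE"

# Internal helpers: seeded substreams and small numeric utilities.

#' Derive a named substream seed from a run seed
#'
#' All randomness in the package flows from a single run seed; each purpose
#' (phantom noise, note filler, parameter init, ...) draws from its own
#' deterministic substream so any component can be regenerated in isolation.
#'
#' @param seed Integer run seed.
#' @param purpose Character tag naming the substream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(1L, "phantom")
substream_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(purpose))
  codes <- utf8ToInt(purpose)
  h <- as.double(seed) %% 2147483647
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
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

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Clamp-and-round to the integer intensity range of an L-level image.
quantize <- function(x, L = 256L) {
  matrix(as.integer(clamp(round(x), 0, L - 1L)), nrow = nrow(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
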