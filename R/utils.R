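# small internal helpers shared across modules

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# trapezoid integral of y over x (x strictly increasing)
trapz_integral <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (any(diff(x) <= 0)) {
    stop("x coordinates must be strictly increasing", call. = FALSE)
  }
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; if seed is NULL the expression uses the ambient RNG stream.
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# derive a reproducible substream seed (kept within 32-bit integer range)
substream_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
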