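# internal helpers shared across modules

# Deterministic per-stage seed derived from the master seed, so each pipeline
# stage draws from its own named substream. Kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(stage)
  h <- sum(chars * seq_along(chars)) * 131
  out <- ((as.numeric(seed) %% 2147483647) * 48271 + h) %% 2147483647
  as.integer(max(out, 1))
}

clip <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

#' Half-up rounding
#'
#' Rounds halves away from zero (R's `round()` rounds half to even), the
#' convention used for the reported contribution percentages. Stored values
#' are never rounded.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- rlang::`%||%`
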