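# internal helpers shared across modules

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in tissue
#' reports follow the conventional half-up rule (62.05 -> 62.1), so the
#' breakdown and similarity exporters use this instead.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() with call. = FALSE everywhere; validation errors should read like
# data problems, not like internals.
fail <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
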