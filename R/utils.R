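#' Round half away from zero
#'
#' Presentation rounding for metric tables. Base R's `round()` rounds half to
#' even ("banker's rounding"), so e.g. `round(0.875, 2)` gives 0.87; published
#' clinical tables round half up (0.875 -> 0.88). Full precision is always kept
#' internally; this helper is only used for display columns.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` places.
#' @export
#' @examples
#' round_half_up(0.875, 2) # 0.88
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-12) / m
}

# Derive a stage seed from a base seed; keeps results < 2^31 so they remain
# valid R integers.
derive_seed <- function(base_seed, stage) {
  as.integer((as.numeric(base_seed) * 1009 + 7919 * stage) %% 2147483647)
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# shared argument checks
stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == floor(x)

is_prop <- function(x, lo = 0, hi = 1, open_hi = FALSE) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= lo &&
    (if (open_hi) x < hi else x <= hi)
}
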