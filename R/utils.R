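#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as opposed to the round-half-to-even rule
#' of [base::round()]. Used for all printed percentages and means so that
#' e.g. 67/132 reports as 50.76.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(2.5)            # 3, not 2
#' round_half_up(100 * 67 / 132, 2) # 50.76
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# scalar non-negative count check
is_count <- function(x, allow_zero = TRUE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == trunc(x) &&
    (x > 0 || (allow_zero && x == 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
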