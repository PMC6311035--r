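#' Euclidean projection onto non-increasing sequences
#'
#' Projects a numeric vector onto the cone of non-increasing sequences in the
#' least-squares sense (classical isotonic regression with reversed order,
#' computed by pool-adjacent-violators). This is the proximal building block
#' behind the monotone lag constraint: within each predictor's block of lagged
#' coefficients, magnitudes must not grow with the lag.
#'
#' @param v Numeric vector, all values finite.
#' @return Numeric vector of the same length, non-increasing, minimising
#'   `sum((u - v)^2)` over all non-increasing `u`.
#' @examples
#' project_nonincreasing(c(3, 1))    # already feasible
#' project_nonincreasing(c(1, 3))    # violators pooled to their mean
#' @export
project_nonincreasing <- function(v) {
  if (!is.numeric(v) || length(v) < 1L) {
    stop("`v` must be a numeric vector of length >= 1", call. = FALSE)
  }
  if (!all(is.finite(v))) {
    stop("`v` contains non-finite values", call. = FALSE)
  }
  if (length(v) == 1L) {
    return(as.numeric(v))
  }
  # isoreg fits the non-decreasing least-squares sequence; negate for
  # non-increasing order.
  -stats::isoreg(-as.numeric(v))$yf
}
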