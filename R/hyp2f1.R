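# Gauss hypergeometric function on [0, 1) for real parameters.
#
# Only the parameter ranges arising in the exact splitting threshold are
# needed (c > 0, arguments in [0, 1)); the direct series is used away from
# the unit argument and the Euler transformation
#   2F1(a, b; c; y) = (1-y)^(c-a-b) 2F1(c-a, c-b; c; y)
# near it, which is enough for |y| < 1 at double precision.

hyp2f1_series <- function(a, b, cc, y, max_terms = 5000L) {
  term <- 1; total <- 1
  for (k in 0:max_terms) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * y
    total <- total + term
    if (abs(term) < 1e-16 * abs(total)) return(total)
  }
  total
}

#' Gauss hypergeometric function 2F1 for argument in [0, 1)
#'
#' Series evaluation with the Euler linear transformation applied near the
#' unit argument.  Supports the real-parameter range used by
#' [splitting_threshold_exact()] (`c > 0` and `c - a - b` non-integer or
#' the series terminating before the singularity matters).
#'
#' @param a,b,cc real parameters (`cc > 0`).
#' @param y argument(s) in `[0, 1)` (vectorized).
#' @return Numeric vector of function values.
#' @export
hyp2f1 <- function(a, b, cc, y) {
  stopifnot(cc > 0, all(y >= 0), all(y < 1))
  vapply(y, function(yi) {
    if (yi < 0.7) hyp2f1_series(a, b, cc, yi)
    else (1 - yi)^(cc - a - b) * hyp2f1_series(cc - a, cc - b, cc, yi)
  }, numeric(1))
}
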