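#' Box-Cox transformation
#'
#' One- or two-parameter Box-Cox power transform
#' `g(a) = ((a + offset)^lambda - 1) / lambda`, with the natural logarithm at
#' `lambda = 0`.  The one-parameter form (`offset = 0`) is used by the
#' NCI-style amount model; the two-parameter form by the MSM-style amount
#' model.
#'
#' @param a Non-negative amounts; `a + offset` must be strictly positive.
#' @param lambda Power parameter; 0 means natural log.
#' @param offset Additive offset applied before the power transform.
#' @return Transformed values.
#' @seealso [bc_inverse()]
#' @export
bc_transform <- function(a, lambda, offset = 0) {
  x <- a + offset
  if (any(x <= 0, na.rm = TRUE)) {
    stop_ui("Box-Cox transform requires positive amounts (after offset %g)",
            offset, class = "boxcox_error")
  }
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Inverse Box-Cox transformation with support truncation
#'
#' Back-transforms values from the Box-Cox scale to the amount scale.  For
#' `lambda > 0` the transform's image is bounded below at `-1/lambda`; values
#' at or below that boundary are mapped to amount 0 (the boundary value),
#' which is how out-of-support quadrature nodes are handled throughout the
#' package.  For `lambda < 0` the image is bounded above; values at or beyond
#' the boundary are evaluated at a point just inside it, capping the
#' back-transformed amount.
#'
#' @param y Values on the transformed scale.
#' @param lambda Power parameter; 0 means natural log.
#' @param offset Additive offset used in the forward transform.
#' @return Non-negative amounts.
#' @export
bc_inverse <- function(y, lambda, offset = 0) {
  if (abs(lambda) < 1e-12) {
    out <- exp(y) - offset
  } else {
    base <- lambda * y + 1
    if (lambda > 0) {
      out <- ifelse(base <= 0, 0, base^(1 / lambda) - offset)
    } else {
      # approaching the upper boundary sends the amount to infinity; cap it
      base <- pmax(base, 1e-8)
      out <- base^(1 / lambda) - offset
    }
  }
  pmax(out, 0)
}

# log-Jacobian of the Box-Cox transform, needed when profiling lambda on the
# likelihood of the transformed data
bc_log_jacobian <- function(a, lambda, offset = 0) {
  (lambda - 1) * sum(log(a + offset))
}

# Shapiro-Francia-type normality score: correlation of the order statistics
# with standard normal quantiles.  Used to choose the MSM transform.
normality_score <- function(y) {
  n <- length(y)
  if (n < 3 || stats::sd(y) == 0) return(-Inf)
  stats::cor(sort(y), stats::qnorm(stats::ppoints(n)))
}
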