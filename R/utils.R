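#' Gauss-Hermite quadrature for a standard normal weight
#'
#' Returns nodes and weights such that `sum(w * f(z))` approximates
#' `E[f(Z)]` for `Z ~ N(0, 1)`.
#'
#' @param n Number of nodes.
#' @return A list with numeric vectors `z` (nodes) and `w` (weights summing
#'   to 1).
#' @export
gauss_hermite_normal <- function(n) {
  gh <- pracma::gaussHermite(n)
  list(z = gh$x * sqrt(2), w = gh$w / sqrt(pi))
}

invlogit <- function(x) 1 / (1 + exp(-x))

#' Round half away from zero
#'
#' Table rendering convention: two decimals, ties rounded away from zero
#' (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Package-wide quantile convention: empirical quantile with linear
# interpolation between order statistics (stats::quantile type 7).
qtile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

# Covariate design matrix used by every model: intercept, female indicator,
# standardised age, weekend indicator.  Centering/scale are carried so that
# fits and predictions agree on the same coding.
covariate_matrix <- function(sex, age, is_weekend, age_center = 40, age_scale = 10) {
  cbind(
    intercept = 1,
    female    = as.numeric(sex == "female"),
    age_std   = (age - age_center) / age_scale,
    weekend   = as.numeric(is_weekend)
  )
}

WEEKDAY_WEIGHT <- 5 / 7
WEEKEND_WEIGHT <- 2 / 7

SEASONS <- c("winter", "spring", "summer", "autumn")
DAYS_OF_WEEK <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

stop_ui <- function(fmt, ..., class) {
  stop(structure(
    class = c(class, "usualintake_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
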