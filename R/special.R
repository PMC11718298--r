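# Numerical tolerances used across the package.
.idscale_tol <- list(
  special = 1e-12, # target relative accuracy of special-function evaluations
  root    = 1e-10, # absolute tolerance of inverse-digamma root finding
  d_limit = 1e-8   # |d| below which the Dirichlet-process limit is used
)

#' Inverse of the digamma function
#'
#' Solves \eqn{\psi_0(x) = y} for \eqn{x > 0} by Newton iteration, where
#' \eqn{\psi_0} is [digamma()]. The digamma function is strictly increasing
#' on \eqn{(0, \infty)}, so the inverse is well defined and monotone for any
#' finite \eqn{y}.
#'
#' The starting point follows the usual asymptotic split: for large \eqn{y},
#' \eqn{\psi_0(x) \approx \log x}, so \eqn{x_0 = e^y + 1/2}; for very
#' negative \eqn{y}, \eqn{\psi_0(x) \approx -1/x - \gamma_E}, so
#' \eqn{x_0 = -1/(y + \gamma_E)}.
#'
#' @param y Numeric vector of finite values.
#' @param tol Absolute tolerance on \eqn{|\psi_0(x) - y|}.
#' @param max_iter Iteration cap per element.
#' @return Numeric vector `x` with `digamma(x)` equal to `y` within `tol`.
#' @examples
#' inverse_digamma(digamma(2)) # 2
#' @export
inverse_digamma <- function(y, tol = .idscale_tol$root, max_iter = 100L) {
  if (!is.numeric(y) || any(!is.finite(y))) {
    stop("inverse_digamma() requires finite numeric input", call. = FALSE)
  }
  vapply(y, function(yi) {
    x <- if (yi >= -2.22) exp(yi) + 0.5 else -1 / (yi - digamma(1))
    for (it in seq_len(max_iter)) {
      f <- digamma(x) - yi
      if (abs(f) < tol) return(x)
      step <- f / trigamma(x)
      # Newton step can overshoot below zero for extreme starts; damp it.
      x_new <- x - step
      while (x_new <= 0) {
        step <- step / 2
        x_new <- x - step
      }
      x <- x_new
    }
    if (abs(digamma(x) - yi) < tol * 100) return(x)
    stop(sprintf(
      "inverse_digamma() did not converge for y = %g (last x = %g, residual = %g)",
      yi, x, digamma(x) - yi
    ), call. = FALSE)
  }, numeric(1))
}

# log of the gamma-ratio Gamma(a)/Gamma(b), stable for large arguments
.lgamma_ratio <- function(a, b) lgamma(a) - lgamma(b)

# lgamma(x + c) - lgamma(x) for moderate |c|, stable at very large x where
# direct lgamma differences lose all precision. For x above the switchover
# the Stirling expansion is rearranged so every term is O(c log x):
#   (x - 1/2) log1p(c/x) + c log(x + c) + 1/(12(x+c)) - 1/(12x) - c
.lgamma_shift <- function(x, c) {
  len <- max(length(x), length(c))
  x <- rep_len(x, len); c <- rep_len(c, len)
  big <- x > 1e8
  out <- numeric(len)
  if (any(!big)) out[!big] <- lgamma(x[!big] + c[!big]) - lgamma(x[!big])
  if (any(big)) {
    xb <- x[big]; cb <- c[big]
    out[big] <- (xb - 0.5) * log1p(cb / xb) + cb * log(xb + cb) - cb +
      1 / (12 * (xb + cb)) - 1 / (12 * xb)
  }
  out
}

# digamma(x + c) - digamma(x), stable at very large x:
#   log1p(c/x) + c/(2x(x+c)) + (1/12)(1/x^2 - 1/(x+c)^2)
.digamma_shift <- function(x, c) {
  len <- max(length(x), length(c))
  x <- rep_len(x, len); c <- rep_len(c, len)
  big <- x > 1e8
  out <- numeric(len)
  if (any(!big)) out[!big] <- digamma(x[!big] + c[!big]) - digamma(x[!big])
  if (any(big)) {
    xb <- x[big]; cb <- c[big]
    out[big] <- log1p(cb / xb) + cb / (2 * xb * (xb + cb)) +
      (1 / xb^2 - 1 / (xb + cb)^2) / 12
  }
  out
}
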