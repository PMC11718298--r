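#' Expected correctness under a Pitman-Yor prior
#'
#' Expected fraction of records correctly matched (rank-1 identification
#' rate) in a gallery of `n` records whose anonymity-set frequencies follow
#' a PY(d, alpha) prior:
#' \deqn{E[\kappa(n)] = \frac{1}{nd}\left(
#'   \frac{\Gamma(1+\alpha)\,\Gamma(n+d+\alpha)}{\Gamma(d+\alpha)\,\Gamma(n+\alpha)}
#'   - \alpha\right)}
#' computed with log-gamma differences so that it remains stable for
#' populations up to billions. As \eqn{d \to 0} the expression has the
#' Dirichlet-process limit \eqn{(\alpha/n)(\psi_0(\alpha+n) -
#' \psi_0(\alpha))}, used whenever `|d|` is below the switchover tolerance
#' to avoid catastrophic cancellation in the `1/(nd)` prefactor.
#'
#' @param n Population (gallery) size(s), `n >= 1`; may be non-integer for
#'   large populations such as 7.53e9.
#' @param params A [py_params()] or [info_params()] object.
#' @return Expected correctness in `(0, 1]`, vectorized over `n`;
#'   non-increasing in `n` and equal to 1 at `n = 1`.
#' @examples
#' expected_correctness(1e6, py_params(0.5, 10))
#' @export
expected_correctness <- function(n, params) {
  p <- .as_py(params)
  .check_n(n)
  d <- p$d; a <- p$alpha
  out <- if (abs(d) < .idscale_tol$d_limit) {
    (a / n) * .digamma_shift(a, n)
  } else if (a == 0) {
    exp(-lgamma(d) + .lgamma_shift(n, d)) / (n * d)
  } else {
    # Gamma(1+a)/Gamma(d+a) * Gamma(n+d+a)/Gamma(n+a) = a * exp(delta'),
    # with delta' = [lgamma(n+a+d)-lgamma(n+a)] - [lgamma(a+d)-lgamma(a)];
    # expm1 keeps the subtraction of alpha exact when delta' is tiny.
    a * expm1(.lgamma_shift(n + a, d) - .lgamma_shift(a, d)) / (n * d)
  }
  pmin(pmax(out, 0), 1)
}

#' Expected population uniqueness under a Pitman-Yor prior
#'
#' Expected fraction of records whose auxiliary information is unique in a
#' gallery of `n` records:
#' \deqn{E[\Xi(n)] = \frac{\Gamma(\alpha+1)\,\Gamma(n+d+\alpha-1)}
#'   {\Gamma(d+\alpha)\,\Gamma(n+\alpha)}}
#' For `d = 0` this reduces to \eqn{\alpha/(n+\alpha-1)}.
#'
#' @inheritParams expected_correctness
#' @return Expected uniqueness in `(0, 1]`, vectorized over `n`.
#' @examples
#' expected_uniqueness(2, py_params(0, 1)) # 0.5
#' @export
expected_uniqueness <- function(n, params) {
  p <- .as_py(params)
  .check_n(n)
  d <- p$d; a <- p$alpha
  if (a == 0) {
    # Gamma(alpha + 1) / Gamma(d + alpha) finite: 1 / Gamma(d)
    out <- exp(-lgamma(d) + .lgamma_shift(n, d - 1))
    out[n == 1] <- 1
  } else {
    out <- a * exp(.lgamma_shift(n + a, d - 1) - .lgamma_shift(a, d))
  }
  pmin(pmax(out, 0), 1)
}

#' Expected fraction of k-anonymity violations under a Pitman-Yor prior
#'
#' Expected fraction of records falling in anonymity sets of fewer than `k`
#' records, in a gallery of `n` records with PY(d, alpha) frequencies.
#' Evaluated as the exact finite occupancy sum
#' \deqn{E[V_k(n)] = \sum_{j=1}^{k-1} \binom{n-1}{j-1}
#'   \frac{\Gamma(1+\alpha)}{\Gamma(1-d)\Gamma(\alpha+d)}
#'   B(j - d,\; n - j + \alpha + d)}
#' where the \eqn{j}-th term is the probability that a record shares its
#' set with exactly \eqn{j - 1} of the other \eqn{n - 1} records (the
#' size-biased occupancy distribution of the PY mean intensity). The sum
#' is equivalent to the generalized-hypergeometric closed form and reduces
#' to the expected uniqueness at `k = 2`.
#'
#' @inheritParams expected_correctness
#' @param k Anonymity threshold, `1 <= k <= n`.
#' @return Probability in `[0, 1]`; non-decreasing in `k`; 0 at `k = 1`.
#' @examples
#' expected_kanon_violations(1000, 5, py_params(0.5, 10))
#' @export
expected_kanon_violations <- function(n, k, params) {
  p <- .as_py(params)
  .check_n(n)
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  if (any(k > n)) stop("expected_kanon_violations: k must not exceed n", call. = FALSE)
  if (k == 1) return(rep(0, length(n)))
  d <- p$d; a <- p$alpha
  # log of Gamma(1+a)/Gamma(a+d), stable for large a
  lC <- (if (a == 0) -lgamma(d) else log(a) - .lgamma_shift(a, d)) -
    lgamma(1 - d)
  vapply(n, function(ni) {
    j <- seq_len(k - 1)
    lt <- lchoose(ni - 1, j - 1) + lC +
      lgamma(j - d) + .lgamma_shift(ni + a, d - j)
    min(max(sum(exp(lt)), 0), 1)
  }, numeric(1))
}

.check_n <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1)) {
    stop("population size n must be numeric and >= 1", call. = FALSE)
  }
  invisible(n)
}

#' Frequency vector of anonymity-set probabilities
#'
#' A finite vector of strictly positive probabilities summing to one,
#' representing the (exchangeable, order-free) frequencies with which each
#' anonymity set is drawn.
#'
#' @param p Numeric vector of positive probabilities summing to 1 within
#'   `tol`; renormalized exactly on construction.
#' @param tol Tolerance on `|sum(p) - 1|`.
#' @return An object of class `"frequency_vector"`.
#' @examples
#' frequency_vector(c(0.5, 0.25, 0.25))
#' @export
frequency_vector <- function(p, tol = 1e-8) {
  if (!is.numeric(p) || length(p) < 1 || any(!is.finite(p)) || any(p <= 0)) {
    stop("frequency_vector: all entries must be finite and > 0", call. = FALSE)
  }
  s <- sum(p)
  if (abs(s - 1) > tol) {
    stop(sprintf("frequency_vector: entries sum to %.10g, not 1", s), call. = FALSE)
  }
  structure(as.numeric(p) / s, class = "frequency_vector")
}

.as_freq <- function(freqs) {
  if (inherits(freqs, "frequency_vector")) return(unclass(freqs))
  unclass(frequency_vector(freqs))
}

#' Correctness of exact matching given anonymity-set frequencies
#'
#' For a fixed finite frequency vector \eqn{\pi}, the expected fraction of
#' `n` i.i.d. records correctly matched equals the expected number of
#' occupied anonymity sets divided by `n`:
#' \deqn{\kappa(n) = \frac{1}{n}\sum_i \left[1 - (1 - \pi_i)^n\right]}
#'
#' @param freqs A [frequency_vector()] (or numeric vector summing to 1).
#' @param n Gallery size(s), `n >= 1`.
#' @return Correctness in `(0, 1]`, vectorized over `n`; equal to 1 at `n = 1`.
#' @examples
#' correctness_from_frequencies(rep(0.25, 4), 2) # 0.875
#' @export
correctness_from_frequencies <- function(freqs, n) {
  p <- .as_freq(freqs)
  .check_n(n)
  vapply(n, function(ni) sum(-expm1(ni * log1p(-p))) / ni, numeric(1))
}

#' Uniqueness of exact matching given anonymity-set frequencies
#'
#' Expected fraction of `n` i.i.d. records whose anonymity set contains no
#' other record: \eqn{\Xi(n) = \sum_i \pi_i (1 - \pi_i)^{n-1}}.
#'
#' @inheritParams correctness_from_frequencies
#' @return Uniqueness in `[0, 1]`, vectorized over `n`; equal to 1 at `n = 1`.
#' @examples
#' uniqueness_from_frequencies(c(0.5, 0.5), 2) # 0.5
#' @export
uniqueness_from_frequencies <- function(freqs, n) {
  p <- .as_freq(freqs)
  .check_n(n)
  vapply(n, function(ni) sum(p * exp((ni - 1) * log1p(-p))), numeric(1))
}

#' k-anonymity violations given anonymity-set frequencies
#'
#' Expected fraction of `n` i.i.d. records in anonymity sets of fewer than
#' `k` records. A record drawn into a set of probability \eqn{\pi} shares
#' it with a Binomial(n-1, \eqn{\pi}) number of others, so
#' \deqn{V_k(n) = \sum_i \pi_i \, P(\mathrm{Bin}(n-1, \pi_i) \le k - 2)}
#' which equals the regularized incomplete beta form
#' \eqn{\sum_i \pi_i I_{1-\pi_i}(n-k+1, k-1)}. `k = 1` is defined as 0 and
#' `k = 2` reduces to [uniqueness_from_frequencies()].
#'
#' @inheritParams correctness_from_frequencies
#' @param k Anonymity threshold, `1 <= k <= n`.
#' @return Probability in `[0, 1]`.
#' @export
kanon_from_frequencies <- function(freqs, n, k) {
  p <- .as_freq(freqs)
  .check_n(n)
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  if (any(k > n)) stop("kanon_from_frequencies: k must not exceed n", call. = FALSE)
  if (k == 1) return(rep(0, length(n)))
  vapply(n, function(ni) sum(p * stats::pbinom(k - 2, ni - 1, p)), numeric(1))
}
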