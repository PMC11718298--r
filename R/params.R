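#' Pitman-Yor parameters (discount and concentration)
#'
#' Container for the natural parameterization of the Pitman-Yor process
#' PY(d, alpha): `d` (discount) controls the heaviness of the tail of
#' anonymity-set frequencies, `alpha` (concentration) their diversity.
#'
#' The standard regime is \eqn{0 \le d < 1}, \eqn{\alpha > -d}, the one in
#' which all fitting takes place. Negative discounts (`d < 0`, with
#' \eqn{\alpha > -d}) describe finite, nearly uniform supports and are
#' accepted for forward evaluation of the expected metrics only; such
#' parameters are flagged via the `"extended"` attribute.
#'
#' @param d Discount, `d < 1`.
#' @param alpha Concentration, `alpha > -d`.
#' @return An object of class `"py_params"`.
#' @seealso [info_params()], [info_from_py()], [py_from_info()]
#' @examples
#' py_params(0.5, 1)
#' @export
py_params <- function(d, alpha) {
  stopifnot(is.numeric(d), length(d) == 1, is.numeric(alpha), length(alpha) == 1)
  if (!is.finite(d) || !is.finite(alpha)) {
    stop("py_params: d and alpha must be finite", call. = FALSE)
  }
  if (d >= 1) stop("py_params: discount d must be < 1", call. = FALSE)
  if (alpha <= -d) {
    stop(sprintf("py_params: concentration alpha must exceed -d = %g (got %g)",
                 -d, alpha), call. = FALSE)
  }
  if (d + alpha <= 0) {
    stop("py_params: d + alpha must be positive", call. = FALSE)
  }
  structure(list(d = d, alpha = alpha, extended = d < 0), class = "py_params")
}

#' @export
print.py_params <- function(x, ...) {
  cat(sprintf("Pitman-Yor parameters: d = %.6g, alpha = %.6g%s\n",
              x$d, x$alpha,
              if (x$extended) " (extended regime, d < 0)" else ""))
  invisible(x)
}

#' Information parameterization (entropy and tail complexity)
#'
#' Container for the information reparameterization of the Pitman-Yor prior:
#' `h` is the expected Shannon entropy of the anonymity-set frequency
#' distribution, `gamma` the tail complexity. `gamma = 0` corresponds to a
#' geometric (exponential) tail (the Dirichlet-process limit, `d = 0`),
#' `gamma = 1` to a maximally heavy tail (`alpha = 0`), and `gamma < 0` to
#' finite, nearly uniform supports (extended regime).
#'
#' Entropy is stored internally in natural-log units (nats), in which the
#' digamma identities relating the two parameterizations are exact. Set
#' `units = "bits"` to supply `h` in bits; it is converted on input.
#'
#' @param h Expected Shannon entropy, `h > 0`, in the units given by `units`.
#' @param gamma Tail complexity, `gamma <= 1`.
#' @param units Units of the supplied `h`: `"nats"` (default) or `"bits"`.
#' @return An object of class `"info_params"` with `h` in nats.
#' @examples
#' info_params(40, 0.5, units = "bits")
#' @export
info_params <- function(h, gamma, units = c("nats", "bits")) {
  units <- match.arg(units)
  stopifnot(is.numeric(h), length(h) == 1, is.numeric(gamma), length(gamma) == 1)
  if (!is.finite(h) || h <= 0) {
    stop("info_params: entropy h must be positive and finite", call. = FALSE)
  }
  if (units == "bits") h <- h * log(2)
  if (!is.finite(gamma) || gamma > 1) {
    stop("info_params: tail complexity gamma must be <= 1", call. = FALSE)
  }
  structure(list(h = h, gamma = gamma), class = "info_params")
}

#' @export
print.info_params <- function(x, ...) {
  cat(sprintf("Information parameters: h = %.6g nats (%.6g bits), gamma = %.6g\n",
              x$h, x$h / log(2), x$gamma))
  invisible(x)
}

#' Entropy of an `info_params` object in bits
#' @param info An [info_params()] object.
#' @return The expected entropy in bits.
#' @export
h_bits <- function(info) {
  stopifnot(inherits(info, "info_params"))
  info$h / log(2)
}

#' Map Pitman-Yor parameters to entropy and tail complexity
#'
#' Computes the expected Shannon entropy \eqn{h = \psi_0(\alpha + 1) -
#' \psi_0(1 - d)} (nats) and the tail complexity \eqn{\gamma = (\psi_0(1) -
#' \psi_0(1 - d)) / h} of the anonymity-set frequency distribution under a
#' PY(d, alpha) prior.
#'
#' @param params A [py_params()] object.
#' @return An [info_params()] object.
#' @examples
#' info_from_py(py_params(0.5, 1)) # h = 1 + 2 log 2, gamma = 2 log 2 / h
#' @export
info_from_py <- function(params) {
  stopifnot(inherits(params, "py_params"))
  h <- digamma(params$alpha + 1) - digamma(1 - params$d)
  if (h <= 0) {
    stop("info_from_py: expected entropy is non-positive for these parameters",
         call. = FALSE)
  }
  gamma <- (digamma(1) - digamma(1 - params$d)) / h
  info_params(h, gamma)
}

#' Map entropy and tail complexity to Pitman-Yor parameters
#'
#' Inverts the information reparameterization:
#' \eqn{d = 1 - \psi_0^{-1}(\psi_0(1) - h\gamma)} and
#' \eqn{\alpha = \psi_0^{-1}(\psi_0(1) + h(1 - \gamma)) - 1}.
#' Tiny numerical residues at the exact boundaries `gamma = 0` (where
#' `d = 0`) and `gamma = 1` (where `alpha = 0`) are snapped to the boundary.
#'
#' @param info An [info_params()] object.
#' @return A [py_params()] object; round-trips with [info_from_py()] to
#'   within numerical tolerance.
#' @examples
#' py_from_info(info_params(1 + 2 * log(2), 2 * log(2) / (1 + 2 * log(2))))
#' @export
py_from_info <- function(info) {
  stopifnot(inherits(info, "info_params"))
  psi1 <- digamma(1)
  u <- inverse_digamma(psi1 - info$h * info$gamma)
  v <- inverse_digamma(psi1 + info$h * (1 - info$gamma))
  d <- 1 - u
  alpha <- v - 1
  if (info$gamma == 0 && abs(d) < 1e-10) d <- 0
  if (info$gamma == 1 && abs(alpha) < 1e-10) alpha <- 0
  if (d >= 1 || alpha <= -d || d + alpha <= 0) {
    stop(sprintf(
      "py_from_info: (h = %g, gamma = %g) maps outside the supported regime (d = %g, alpha = %g)",
      info$h, info$gamma, d, alpha), call. = FALSE)
  }
  py_params(d, alpha)
}

# Coerce either parameterization to py_params.
.as_py <- function(params) {
  if (inherits(params, "py_params")) return(params)
  if (inherits(params, "info_params")) return(py_from_info(params))
  stop("expected a 'py_params' or 'info_params' object", call. = FALSE)
}
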