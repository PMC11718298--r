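#' Read anonymity-set counts from CSV
#'
#' Expects a two-column CSV with header `set_size,count`, one row per
#' distinct set size.
#'
#' @param path Path to the CSV file.
#' @return An [anonymity_counts()] object.
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) stop("read_counts_csv: no such file: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("set_size", "count") %in% names(df))) {
    stop("read_counts_csv: expected columns 'set_size' and 'count'",
         call. = FALSE)
  }
  anonymity_counts(df$set_size, df$count)
}

#' Write anonymity-set counts to CSV
#'
#' Writes the canonical `set_size,count` representation, ordered by set
#' size, so that read/write round-trips are byte-identical.
#'
#' @param counts An [anonymity_counts()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(counts, path) {
  stopifnot(inherits(counts, "anonymity_counts"))
  df <- data.frame(set_size = counts$table$size, count = counts$table$m)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a correctness curve from CSV
#'
#' Expects columns `n,kappa` with an optional third column `reps`.
#'
#' @param path Path to the CSV file.
#' @return A [correctness_curve()].
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) stop("read_curve_csv: no such file: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("n", "kappa") %in% names(df))) {
    stop("read_curve_csv: expected columns 'n' and 'kappa'", call. = FALSE)
  }
  correctness_curve(df$n, df$kappa, reps = df$reps)
}

#' Write a correctness curve to CSV
#'
#' @param curve A [correctness_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "correctness_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a Pitman-Yor fit to JSON
#'
#' Writes the standard fit schema: `h_nats`, `h_bits`, `gamma`, `d`,
#' `alpha`, `loglik`, `converged`, `kl_bits`, `seed`.
#'
#' @param fit A `"py_fit"` from [fit_map()].
#' @param path Output path.
#' @param kl_bits Optional KL diagnostic (from [kl_ranksize()]).
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, kl_bits = NA_real_, seed = NA_integer_) {
  stopifnot(inherits(fit, "py_fit"))
  obj <- list(h_nats = fit$info$h, h_bits = h_bits(fit$info),
              gamma = fit$info$gamma, d = fit$py$d, alpha = fit$py$alpha,
              loglik = fit$diagnostics$loglik,
              converged = fit$diagnostics$converged,
              identifiable = fit$diagnostics$identifiable,
              kl_bits = kl_bits, seed = seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a serialized Pitman-Yor fit
#'
#' @param path Path to a JSON file written by [write_fit_json()].
#' @return A named list with the fit schema fields.
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) stop("read_fit_json: no such file: ", path,
                               call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
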