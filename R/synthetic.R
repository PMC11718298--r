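#' Synthetic anonymity-set frequency families
#'
#' Builds a finite frequency vector from one of three classical count
#' families spanning a wide range of entropy and tail heaviness:
#' * `"geometric"`: \eqn{\pi_i \propto (1-p)^{i-1} p} — light (exponential)
#'   tails, fitted tail complexity near 0.
#' * `"poisson"`: \eqn{\pi_i \propto \lambda^{i-1} e^{-\lambda}/(i-1)!}
#'   (1-based shift of the Poisson pmf) — concentrated, light tails.
#' * `"zipf"`: \eqn{\pi_i \propto i^{-s}} — heavy tails, fitted tail
#'   complexity approaching 1 as `s` decreases toward 1.
#'
#' Support is truncated where the discarded tail mass falls below
#' `tail_mass_tol`, subject to a hard cap of `max_support` atoms (heavy
#' Zipf tails would otherwise require astronomically large supports); when
#' the cap binds, the result carries attribute `truncated = TRUE`. The
#' vector is renormalized after truncation.
#'
#' @param family One of `"geometric"`, `"poisson"`, `"zipf"`.
#' @param param Family parameter: success probability `p` in (0, 1) for
#'   geometric, rate `lambda > 0` for Poisson, exponent `s > 1` for Zipf.
#' @param tail_mass_tol Truncation tolerance on discarded mass.
#' @param max_support Cap on the number of atoms.
#' @return A [frequency_vector()] with attributes `family`, `param`,
#'   `truncated`.
#' @examples
#' make_frequencies("zipf", 1, max_support = 3) # (6/11, 3/11, 2/11)
#' @export
make_frequencies <- function(family = c("geometric", "poisson", "zipf"),
                             param, tail_mass_tol = 1e-9, max_support = 1e6) {
  family <- match.arg(family)
  stopifnot(is.numeric(param), length(param) == 1, is.finite(param))
  truncated <- FALSE
  if (family == "geometric") {
    if (param <= 0 || param >= 1) {
      stop("make_frequencies: geometric p must lie in (0, 1)", call. = FALSE)
    }
    M <- ceiling(log(tail_mass_tol) / log1p(-param))
    if (M > max_support) { M <- max_support; truncated <- TRUE }
    p <- stats::dgeom(seq_len(M) - 1, param)
  } else if (family == "poisson") {
    if (param <= 0) stop("make_frequencies: poisson lambda must be > 0",
                         call. = FALSE)
    M <- stats::qpois(1 - tail_mass_tol, param) + 1
    if (M > max_support) { M <- max_support; truncated <- TRUE }
    p <- stats::dpois(seq_len(M) - 1, param)
  } else {
    if (param <= 0) stop("make_frequencies: zipf exponent s must be > 0",
                         call. = FALSE)
    M <- if (param > 1) {
      # integral tail bound: sum_{i>M} i^-s < M^(1-s)/(s-1)
      ceiling((tail_mass_tol * (param - 1))^(-1 / (param - 1)))
    } else Inf
    if (M > max_support) { M <- max_support; truncated <- TRUE }
    p <- exp(-param * log(seq_len(M)))
  }
  out <- frequency_vector(p[p > 0] / sum(p[p > 0]), tol = Inf)
  attr(out, "family") <- family
  attr(out, "param") <- param
  attr(out, "truncated") <- truncated
  out
}

#' Sample a gallery from fixed anonymity-set frequencies
#'
#' Draws `n` records i.i.d. from a categorical distribution over anonymity
#' sets and returns the occupancy multiset.
#'
#' @param freqs A [frequency_vector()].
#' @param n Number of records, `n >= 1`.
#' @param seed Integer seed.
#' @return An [anonymity_counts()] object.
#' @export
sample_gallery <- function(freqs, n, seed = NULL) {
  p <- .as_freq(freqs)
  stopifnot(n >= 1, n == round(n))
  withr::with_seed(if (is.null(seed)) 1L else seed, {
    draws <- sample.int(length(p), n, replace = TRUE, prob = p)
    occ <- tabulate(draws, nbins = length(p))
    anonymity_counts(occ[occ > 0])
  })
}

#' Generate a corpus of synthetic data collections
#'
#' Builds `n_collections` synthetic galleries by drawing a family parameter
#' log-uniformly within its configured range, constructing the frequency
#' vector, and sampling `n` i.i.d. records. Families are cycled in order.
#' The master seed is expanded deterministically into per-collection seeds,
#' so the same master seed always reproduces the identical corpus and
#' manifest.
#'
#' @param n_collections Number of collections.
#' @param families Families to cycle through.
#' @param ranges Named list of parameter ranges (length-2 numeric vectors)
#'   per family. Defaults: geometric `p` in `[0.001, 0.5]`, Poisson
#'   `lambda` in `[1, 1000]`, Zipf `s` in `[1.01, 3]`.
#' @param n Records per gallery.
#' @param master_seed Integer master seed.
#' @return A list of class `"synthetic_corpus"`: `collections` (named list
#'   of [anonymity_counts()]) and `manifest` (data.frame with family,
#'   parameter, n, seed per collection).
#' @export
make_corpus <- function(n_collections,
                        families = c("geometric", "poisson", "zipf"),
                        ranges = list(geometric = c(0.001, 0.5),
                                      poisson = c(1, 1000),
                                      zipf = c(1.01, 3)),
                        n = 1e5, master_seed = 1L) {
  stopifnot(n_collections >= 0, n >= 1)
  if (n_collections == 0) {
    return(structure(list(collections = list(),
                          manifest = data.frame()),
                     class = "synthetic_corpus"))
  }
  fam <- rep_len(families, n_collections)
  seeds <- withr::with_seed(master_seed,
                            sample.int(.Machine$integer.max - 1L, n_collections))
  collections <- vector("list", n_collections)
  manifest <- vector("list", n_collections)
  for (i in seq_len(n_collections)) {
    rg <- ranges[[fam[i]]]
    param <- withr::with_seed(seeds[i],
                              exp(stats::runif(1, log(rg[1]), log(rg[2]))))
    freqs <- make_frequencies(fam[i], param)
    collections[[i]] <- sample_gallery(freqs, n, seed = seeds[i] %% 100000L + 1L)
    manifest[[i]] <- data.frame(
      collection = sprintf("%s_%03d", fam[i], i), family = fam[i],
      param = param, n = n, seed = seeds[i],
      truncated = attr(freqs, "truncated"))
  }
  manifest <- do.call(rbind, manifest)
  names(collections) <- manifest$collection
  structure(list(collections = collections, manifest = manifest),
            class = "synthetic_corpus")
}

#' Write a synthetic corpus to disk
#'
#' Emits one `set_size,count` CSV per collection plus a JSON manifest
#' recording family, parameter, gallery size, and seed for each, so a
#' corpus can be regenerated or consumed by the `evaluate` command-line
#' subcommand.
#'
#' @param corpus A `"synthetic_corpus"` from [make_corpus()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- corpus$manifest
  if (nrow(manifest) > 0) {
    manifest$file <- paste0(manifest$collection, ".csv")
    for (i in seq_along(corpus$collections)) {
      write_counts_csv(corpus$collections[[i]],
                       file.path(dir, manifest$file[i]))
    }
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("Synthetic corpus of %d collections\n", length(x$collections)))
  if (nrow(x$manifest) > 0) print(utils::head(x$manifest), row.names = FALSE)
  invisible(x)
}
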