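#' Log-likelihood of an anonymity-set partition under PY(d, alpha)
#'
#' The exchangeable partition probability function (EPPF) of the Pitman-Yor
#' process, evaluated on the observed multiset of anonymity-set sizes:
#' \deqn{\log P = \sum_{i=1}^{K-1}\log(\alpha + i d)
#'   - \sum_{j=1}^{n-1}\log(\alpha + j)
#'   + \sum_{\mathrm{sets}}\left[\log\Gamma(s - d) - \log\Gamma(1 - d)\right]}
#' The size multiset is exactly the sufficient statistic for partition data,
#' so this is the natural likelihood for fitting the prior to empirical
#' anonymity-set frequencies.
#'
#' @param counts An [anonymity_counts()] object.
#' @param params A [py_params()] object with `0 <= d < 1`.
#' @return The log partition probability; `-Inf` at boundary poles (e.g.
#'   `d -> 1` with sets of size 2 or more) rather than an error.
#' @examples
#' eppf_log_likelihood(anonymity_counts(c(1, 1)), py_params(0.5, 1)) # log 0.75
#' @export
eppf_log_likelihood <- function(counts, params) {
  stopifnot(inherits(counts, "anonymity_counts"), inherits(params, "py_params"))
  d <- params$d; a <- params$alpha
  if (d < 0) stop("eppf_log_likelihood: requires the standard regime d >= 0",
                  call. = FALSE)
  n <- counts$N; K <- counts$K
  # prod_{i=1}^{K-1} (alpha + i d)
  t1 <- if (K == 1) 0
        else if (d == 0) (K - 1) * log(a)
        else (K - 1) * log(d) + lgamma(a / d + K) - lgamma(a / d + 1)
  # prod_{j=1}^{n-1} (alpha + j)
  t2 <- lgamma(a + n) - lgamma(a + 1)
  # per-set (1 - d)_{s - 1} factors
  s <- counts$table$size; mult <- counts$table$m
  t3 <- sum(mult * (lgamma(s - d) - lgamma(1 - d)))
  out <- t1 - t2 + t3
  if (is.nan(out)) -Inf else out
}

#' Configuration for partition-likelihood fitting
#'
#' @param d_max Upper bound of the discount search range (open at 1).
#' @param log_alpha_range Search range for `log(alpha)`.
#' @param reltol Relative convergence tolerance of the simplex search.
#' @param maxit Iteration cap per start.
#' @param log_prior Optional function `(d, alpha) -> log prior density`;
#'   `NULL` (default) is a flat prior, i.e. bounded maximum likelihood.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(d_max = 0.999, log_alpha_range = c(-6, 30),
                       reltol = 1e-10, maxit = 2000L, log_prior = NULL) {
  stopifnot(d_max > 0, d_max < 1, length(log_alpha_range) == 2,
            diff(log_alpha_range) > 0)
  structure(list(d_max = d_max, log_alpha_range = log_alpha_range,
                 reltol = reltol, maxit = maxit, log_prior = log_prior),
            class = "fit_config")
}

# Deterministic multistart lattice in (d, log alpha).
.fit_starts <- data.frame(
  d         = c(0.05, 0.25, 0.50, 0.75, 0.95),
  log_alpha = c(0,    3,    6,    9,    12)
)

#' Fit the Pitman-Yor prior to anonymity-set counts
#'
#' Maximizes the [eppf_log_likelihood()] (plus the configured log-prior)
#' over the standard regime by derivative-free Nelder-Mead simplex search
#' with deterministic multistarts on a coarse (d, log alpha) lattice. The
#' search runs in an unconstrained transform of the bounded (d, log alpha)
#' box; the optimum is reported in the information parameterization
#' (entropy and tail complexity) alongside the natural parameters.
#'
#' @param counts An [anonymity_counts()] object with at least 2 records.
#' @param config A [fit_config()].
#' @return A list of class `"py_fit"` with elements `info`
#'   ([info_params()]), `py` ([py_params()]), and `diagnostics` (log
#'   likelihood, restarts, convergence and boundary flags).
#' @examples
#' cts <- sample_crp(2000, py_params(0.5, 10), seed = 1)
#' fit_map(cts)$py
#' @export
fit_map <- function(counts, config = fit_config()) {
  stopifnot(inherits(counts, "anonymity_counts"))
  if (counts$N < 2) stop("fit_map: at least 2 records are required", call. = FALSE)
  lo <- config$log_alpha_range[1]; hi <- config$log_alpha_range[2]
  to_box <- function(t) {
    d <- config$d_max * stats::plogis(t[1])
    la <- lo + (hi - lo) * stats::plogis(t[2])
    c(d, exp(la))
  }
  from_box <- function(d, la) {
    c(stats::qlogis(d / config$d_max), stats::qlogis((la - lo) / (hi - lo)))
  }
  objective <- function(t) {
    p <- to_box(t)
    ll <- eppf_log_likelihood(counts, py_params(p[1], p[2]))
    if (!is.null(config$log_prior)) ll <- ll + config$log_prior(p[1], p[2])
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  best <- NULL
  n_conv <- 0L
  for (i in seq_len(nrow(.fit_starts))) {
    t0 <- from_box(.fit_starts$d[i], .fit_starts$log_alpha[i])
    opt <- stats::optim(t0, objective, method = "Nelder-Mead",
                        control = list(reltol = config$reltol,
                                       maxit = config$maxit))
    if (opt$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (n_conv == 0L) {
    stop("fit_map: no simplex start converged; diagnostics: best value ",
         best$value, call. = FALSE)
  }
  p <- to_box(best$par)
  d_hat <- p[1]; alpha_hat <- p[2]
  at_bound <- d_hat > 0.995 * config$d_max ||
    log(alpha_hat) > hi - 0.5 || log(alpha_hat) < lo + 0.5
  all_singletons <- all(counts$table$size == 1)
  one_set <- counts$K == 1
  py <- py_params(d_hat, alpha_hat)
  structure(list(
    info = info_from_py(py),
    py = py,
    diagnostics = list(
      loglik = -best$value,
      restarts = nrow(.fit_starts),
      n_converged = n_conv,
      converged = best$convergence == 0,
      at_boundary = at_bound,
      identifiable = !(all_singletons || one_set || at_bound)
    )
  ), class = "py_fit")
}

#' @export
print.py_fit <- function(x, ...) {
  cat(sprintf(
    "Pitman-Yor fit: h = %.4g nats (%.4g bits), gamma = %.4g  [d = %.4g, alpha = %.4g]\n",
    x$info$h, h_bits(x$info), x$info$gamma, x$py$d, x$py$alpha))
  cat(sprintf("  loglik = %.4f, converged = %s, identifiable = %s\n",
              x$diagnostics$loglik, x$diagnostics$converged,
              x$diagnostics$identifiable))
  invisible(x)
}

#' Sample a Pitman-Yor partition by the Chinese restaurant construction
#'
#' Seats `n` customers sequentially: customer `i + 1` opens a new set with
#' probability \eqn{(\alpha + K d)/(\alpha + i)} (with `K` sets open) and
#' otherwise joins an existing set with probability proportional to its
#' size minus the discount. Existing-set selection uses size-proportional
#' proposal with rejection, keeping each step O(1).
#'
#' @param n Number of records, `n >= 1`.
#' @param params A [py_params()] object in the standard regime.
#' @param seed Integer seed for reproducibility.
#' @return An [anonymity_counts()] object.
#' @export
sample_crp <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "py_params"))
  if (params$d < 0) stop("sample_crp: requires the standard regime d >= 0",
                         call. = FALSE)
  stopifnot(n >= 1, n == round(n))
  d <- params$d; a <- params$alpha
  withr::with_seed(if (is.null(seed)) 1L else seed, {
    labels <- integer(n)
    sizes <- integer(0)
    labels[1] <- 1L
    sizes <- 1L
    K <- 1L
    if (n >= 2) {
      for (i in 2:n) {
        if (stats::runif(1) < (a + K * d) / (a + i - 1)) {
          K <- K + 1L
          sizes[K] <- 1L
          labels[i] <- K
        } else {
          repeat {
            j <- labels[sample.int(i - 1L, 1L)]
            if (d == 0 || stats::runif(1) < (sizes[j] - d) / sizes[j]) break
          }
          sizes[j] <- sizes[j] + 1L
          labels[i] <- j
        }
      }
    }
    anonymity_counts(sizes)
  })
}

#' Sample anonymity-set frequencies by stick breaking
#'
#' Draws a frequency vector from PY(d, alpha) via its stick-breaking
#' representation: \eqn{V_i \sim \mathrm{Beta}(1 - d, \alpha + i d)},
#' \eqn{\pi_i = V_i \prod_{j < i}(1 - V_j)}, truncated once the remaining
#' stick mass falls below `tail_mass_tol` and renormalized.
#'
#' @param params A [py_params()] object in the standard regime.
#' @param tail_mass_tol Remaining-mass truncation tolerance.
#' @param max_atoms Cap on the number of atoms; if reached before the
#'   tolerance, the result carries attribute `truncated = TRUE`.
#' @param seed Integer seed.
#' @return A [frequency_vector()] (unsorted, in stick order).
#' @export
sample_stick_breaking <- function(params, tail_mass_tol = 1e-8,
                                  max_atoms = 1e5, seed = NULL) {
  stopifnot(inherits(params, "py_params"))
  if (params$d < 0) stop("sample_stick_breaking: requires d >= 0", call. = FALSE)
  d <- params$d; a <- params$alpha
  withr::with_seed(if (is.null(seed)) 1L else seed, {
    pi_out <- numeric(0)
    log_rem <- 0 # log of remaining stick mass
    i <- 0L
    chunk <- 256L
    truncated <- TRUE
    while (length(pi_out) < max_atoms) {
      v <- stats::rbeta(chunk, 1 - d, a + (i + seq_len(chunk)) * d)
      # guard against exact 0/1 draws at extreme shapes
      v <- pmin(pmax(v, 1e-300), 1 - 1e-16)
      lp <- log_rem + cumsum(c(0, log1p(-v[-chunk]))) + log(v)
      pi_out <- c(pi_out, exp(lp))
      log_rem <- log_rem + sum(log1p(-v))
      i <- i + chunk
      if (exp(log_rem) < tail_mass_tol) {
        truncated <- FALSE
        break
      }
    }
    out <- frequency_vector(pi_out[pi_out > 0] / sum(pi_out[pi_out > 0]),
                            tol = Inf)
    attr(out, "truncated") <- truncated
    out
  })
}

#' Posterior-predictive rank-size envelope
#'
#' Simulates galleries from fitted Pitman-Yor parameters (stick-breaking
#' frequencies, then `n` i.i.d. records per replicate), computes the
#' rank-size distribution of anonymity-set sizes in each, and returns
#' per-rank quantiles. Used as a posterior-predictive check that the fitted
#' prior reproduces the shape of the empirical size distribution.
#'
#' @param params A [py_params()] object.
#' @param n Gallery size per replicate.
#' @param reps Number of replicates (at least 100 for stable 95% bands).
#' @param quantiles Quantile levels of the envelope.
#' @param seed Integer seed.
#' @return A data.frame with column `rank` and one column per quantile.
#' @export
posterior_predictive_bands <- function(params, n, reps = 200L,
                                       quantiles = c(0.025, 0.5, 0.975),
                                       seed = NULL) {
  stopifnot(inherits(params, "py_params"), n >= 1, reps >= 1)
  seed <- if (is.null(seed)) 1L else seed
  draws <- lapply(seq_len(reps), function(r) {
    freqs <- sample_stick_breaking(params, seed = seed + 7L * r)
    cts <- sample_gallery(freqs, n, seed = seed + 7L * r + 3L)
    sort(.set_sizes(cts), decreasing = TRUE)
  })
  max_rank <- max(lengths(draws))
  mat <- vapply(draws, function(x) c(x, rep(0, max_rank - length(x))),
                numeric(max_rank))
  mat <- matrix(mat, nrow = max_rank)
  env <- t(apply(mat, 1, stats::quantile, probs = quantiles))
  out <- data.frame(rank = seq_len(max_rank), env, check.names = FALSE)
  names(out) <- c("rank", paste0("q", quantiles))
  out
}

#' Kullback-Leibler divergence between discrete distributions, in bits
#'
#' \eqn{D_{KL}(P \| Q) = \sum_i P_i \log_2(P_i / Q_i)}, with the convention
#' that terms with \eqn{P_i = 0} contribute zero and any \eqn{P_i > 0}
#' with \eqn{Q_i = 0} yields `Inf`.
#'
#' @param p,q Numeric probability vectors of equal length (renormalized).
#' @return Non-negative divergence in bits.
#' @examples
#' kl_divergence_bits(c(0.5, 0.5), c(0.25, 0.75)) # ~0.2075
#' @export
kl_divergence_bits <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  p <- p / sum(p); q <- q / sum(q)
  nz <- p > 0
  if (any(q[nz] == 0)) return(Inf)
  sum(p[nz] * (log2(p[nz]) - log2(q[nz])))
}

#' KL divergence of the empirical rank-size distribution from the fitted predictive
#'
#' Compares the empirical rank-size distribution of anonymity-set sizes
#' (sorted set sizes divided by the record count) with the mean predictive
#' rank-size distribution obtained by simulating galleries of `n` records
#' from the fitted Pitman-Yor parameters, in bits. Simulation uses the
#' Chinese restaurant construction, whose partition law is exactly that of
#' the fitted prior.
#'
#' @param empirical An [anonymity_counts()] object.
#' @param fitted A [py_params()] object.
#' @param n Gallery size per predictive replicate (defaults to the
#'   empirical record count).
#' @param reps Number of predictive replicates.
#' @param seed Integer seed.
#' @return A list with `kl_bits` (non-negative, possibly `Inf`) and
#'   `support_overlap` (`FALSE` when the predictive never produced as many
#'   anonymity sets as observed, so some empirical ranks have predictive
#'   mass zero).
#' @export
kl_ranksize <- function(empirical, fitted, n = empirical$N, reps = 100L,
                        seed = NULL) {
  stopifnot(inherits(empirical, "anonymity_counts"), inherits(fitted, "py_params"))
  seed <- if (is.null(seed)) 1L else seed
  p_emp <- sort(.set_sizes(empirical), decreasing = TRUE) / empirical$N
  pred <- numeric(0)
  for (r in seq_len(reps)) {
    cts <- sample_crp(n, fitted, seed = seed + r)
    rs <- sort(.set_sizes(cts), decreasing = TRUE) / cts$N
    top <- max(length(rs), length(pred))
    pred <- c(pred, numeric(top - length(pred))) +
      c(rs, numeric(top - length(rs)))
  }
  pred <- pred / reps
  top <- max(length(p_emp), length(pred))
  p <- c(p_emp, numeric(top - length(p_emp)))
  q <- c(pred, numeric(top - length(pred)))
  overlap <- all(q[p > 0] > 0)
  kl <- if (!overlap) Inf else kl_divergence_bits(p, q)
  list(kl_bits = kl, support_overlap = overlap)
}
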