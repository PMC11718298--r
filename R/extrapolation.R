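#' Correctness curve
#'
#' Ordered measurements of identification correctness against gallery size,
#' e.g. as reported by an identification study or produced by
#' [subsampled_correctness_curve()].
#'
#' @param n Strictly increasing integer gallery sizes.
#' @param kappa Correctness values in `[0, 1]`, one per size.
#' @param reps Optional replicate counts per point.
#' @return A data.frame of class `"correctness_curve"` with columns `n`,
#'   `kappa` and optionally `reps`.
#' @export
correctness_curve <- function(n, kappa, reps = NULL) {
  stopifnot(is.numeric(n), is.numeric(kappa), length(n) == length(kappa),
            length(n) >= 1)
  if (any(diff(n) <= 0)) {
    stop("correctness_curve: gallery sizes must be strictly increasing",
         call. = FALSE)
  }
  if (any(kappa < 0 | kappa > 1)) {
    stop("correctness_curve: kappa values must lie in [0, 1]", call. = FALSE)
  }
  df <- data.frame(n = as.numeric(n), kappa = as.numeric(kappa))
  if (!is.null(reps)) df$reps <- as.numeric(reps)
  structure(df, class = c("correctness_curve", "data.frame"))
}

#' Log-weighted quadratic loss of a correctness model
#'
#' The fitting loss for measurement-based extrapolation:
#' \deqn{R(h, \gamma) = \sum_i \log(n_i)\,
#'   [\hat\kappa(n_i) - E[\kappa(n_i) \mid h, \gamma]]^2}
#' The logarithmic weights put more weight on larger gallery sizes, whose
#' correctness measurements are more precise. Points with `n = 1` carry
#' zero log-weight (and \eqn{\kappa(1) \equiv 1}); they are skipped with a
#' warning.
#'
#' @param info An [info_params()] object.
#' @param curve A [correctness_curve()] with at least 2 points.
#' @return Non-negative loss; zero iff the model interpolates every point.
#' @export
pyc_mb_loss <- function(info, curve) {
  stopifnot(inherits(info, "info_params"), inherits(curve, "correctness_curve"))
  use <- curve$n >= 2
  if (any(!use)) {
    warning("pyc_mb_loss: points with n = 1 carry zero weight and are skipped")
  }
  if (sum(use) < 1) stop("pyc_mb_loss: no usable points (all n < 2)", call. = FALSE)
  n <- curve$n[use]; k <- curve$kappa[use]
  model <- expected_correctness(n, info)
  sum(log(n) * (k - model)^2)
}

#' Configuration for curve fitting
#'
#' @param h_range Search range for entropy `h`, in nats.
#' @param gamma_range Search range for tail complexity.
#' @param reltol Relative convergence tolerance of the simplex search.
#' @param maxit Iteration cap per start.
#' @param n_starts Per-axis size of the multistart lattice.
#' @return A list of class `"mb_config"`.
#' @export
mb_config <- function(h_range = c(1e-3, 120), gamma_range = c(0, 1),
                      reltol = 1e-10, maxit = 1000L, n_starts = 4L) {
  structure(list(h_range = h_range, gamma_range = gamma_range,
                 reltol = reltol, maxit = maxit, n_starts = n_starts),
            class = "mb_config")
}

.fit_result <- function(model, params, loss, converged, curve, flags = list()) {
  structure(list(model = model, params = params, loss = loss,
                 converged = converged,
                 train_range = range(curve$n), flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: loss = %.6g, converged = %s, trained on n in [%g, %g]\n",
              x$model, x$loss, x$converged, x$train_range[1], x$train_range[2]))
  str(x$params, give.attr = FALSE)
  invisible(x)
}

#' Fit the Pitman-Yor correctness model to a measured curve
#'
#' Measurement-based extrapolation: minimizes [pyc_mb_loss()] over
#' `(h, gamma)` within bounds, by Nelder-Mead simplex search from a
#' deterministic multistart lattice. Ties in the final loss (within 1e-12)
#' are broken toward the smallest `h`, then the smallest `gamma`, so the
#' result is deterministic.
#'
#' @param curve A [correctness_curve()] with at least 2 points with `n >= 2`.
#' @param config An [mb_config()].
#' @return A `"fit_result"` with `model = "PYC"` and fitted
#'   `params$h` (nats), `params$gamma`.
#' @export
fit_pyc_mb <- function(curve, config = mb_config()) {
  stopifnot(inherits(curve, "correctness_curve"))
  usable <- sum(curve$n >= 2)
  if (usable < 2) stop("fit_pyc_mb: at least 2 points with n >= 2 are required",
                       call. = FALSE)
  curve2 <- curve[curve$n >= 2, , drop = FALSE]
  class(curve2) <- class(curve)
  hr <- config$h_range; gr <- config$gamma_range
  if (all(curve2$kappa == 1)) {
    # any entropy large enough to keep kappa at 1 over the training range
    # attains zero loss: the curve is uninformative, report the bound
    info <- info_params(hr[2], gr[1])
    return(.fit_result("PYC", list(h = hr[2], gamma = gr[1]),
                       suppressWarnings(pyc_mb_loss(info, curve2)), TRUE,
                       curve2,
                       flags = list(h_at_bound = TRUE, degenerate = TRUE)))
  }
  to_box <- function(t) c(
    hr[1] + (hr[2] - hr[1]) * stats::plogis(t[1]),
    gr[1] + (gr[2] - gr[1]) * stats::plogis(t[2])
  )
  from_box <- function(h, g) c(
    stats::qlogis((h - hr[1]) / (hr[2] - hr[1])),
    stats::qlogis((g - gr[1]) / (gr[2] - gr[1]))
  )
  objective <- function(t) {
    p <- to_box(t)
    loss <- tryCatch(
      suppressWarnings(pyc_mb_loss(info_params(p[1], p[2]), curve2)),
      error = function(e) Inf)
    if (!is.finite(loss)) 1e12 else loss
  }
  ns <- config$n_starts
  h0 <- exp(seq(log(max(hr[1], 0.5)), log(hr[2] * 0.75), length.out = ns))
  g0 <- seq(gr[1] + 0.05 * diff(gr), gr[2] - 0.05 * diff(gr), length.out = ns)
  cands <- list()
  for (h in h0) for (g in g0) {
    opt <- stats::optim(from_box(h, g), objective, method = "Nelder-Mead",
                        control = list(reltol = config$reltol,
                                       maxit = config$maxit))
    if (opt$convergence != 0) { # restart the simplex once from the optimum
      opt2 <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                           control = list(reltol = config$reltol,
                                          maxit = config$maxit))
      if (opt2$value <= opt$value) opt <- opt2
    }
    p <- to_box(opt$par)
    cands[[length(cands) + 1]] <- list(h = p[1], gamma = p[2],
                                       loss = opt$value,
                                       converged = opt$convergence == 0)
  }
  losses <- vapply(cands, `[[`, numeric(1), "loss")
  tied <- which(losses <= min(losses) + 1e-12)
  hs <- vapply(cands[tied], `[[`, numeric(1), "h")
  gs <- vapply(cands[tied], `[[`, numeric(1), "gamma")
  pick <- tied[order(hs, gs)[1]]
  best <- cands[[pick]]
  at_upper <- best$h > 0.99 * hr[2]
  .fit_result("PYC", list(h = best$h, gamma = best$gamma), best$loss,
              best$converged, curve2,
              flags = list(h_at_bound = at_upper,
                           degenerate = all(curve2$kappa == 1)))
}

#' Fit a baseline correctness model
#'
#' Baseline comparators fitted under the same log-weighted quadratic loss
#' as the Pitman-Yor model:
#' * `"ENT"` — entropy-only rule of thumb: the Pitman-Yor form restricted
#'   to `gamma = 0` (one free parameter, `h`), fitted by golden-section
#'   search.
#' * `"EXP"` — exponential decay `kappa(n) = min(1, a e^{-b n})`.
#' * `"POL"` — power law `kappa(n) = min(1, a n^{-b})`.
#' * `"RND"` — uninformed baseline whose forecasts are drawn uniformly on
#'   `[0, kappa(n_t)]`, where `n_t` is the largest training size; seeded.
#'
#' @param curve A [correctness_curve()].
#' @param kind One of `"ENT"`, `"EXP"`, `"POL"`, `"RND"`.
#' @param config An [mb_config()] (used by ENT/EXP/POL).
#' @param seed Seed for the `"RND"` baseline's forecasts.
#' @return A `"fit_result"`.
#' @export
fit_baseline <- function(curve, kind = c("ENT", "EXP", "POL", "RND"),
                         config = mb_config(), seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(curve, "correctness_curve"))
  if (kind == "RND") {
    kt <- curve$kappa[nrow(curve)]
    return(.fit_result("RND",
                       list(kappa_max = kt, seed = if (is.null(seed)) 1L else seed),
                       NA_real_, TRUE, curve))
  }
  curve2 <- curve[curve$n >= 2, , drop = FALSE]
  class(curve2) <- class(curve)
  if (nrow(curve2) < 2) stop("fit_baseline: at least 2 points with n >= 2 required",
                             call. = FALSE)
  n <- curve2$n; k <- curve2$kappa; w <- log(n)
  if (kind == "ENT") {
    hr <- config$h_range
    f <- function(h) sum(w * (k - expected_correctness(n, info_params(h, 0)))^2)
    opt <- stats::optimize(f, hr, tol = 1e-10)
    return(.fit_result("ENT", list(h = opt$minimum, gamma = 0), opt$objective,
                       TRUE, curve2,
                       flags = list(h_at_bound = opt$minimum > 0.99 * hr[2])))
  }
  # EXP / POL: two-parameter decay laws, searched in log-parameter space.
  predict_fun <- if (kind == "EXP") {
    function(p, n) pmin(1, exp(log(p[1]) - p[2] * n))
  } else {
    function(p, n) pmin(1, exp(log(p[1]) - p[2] * log(n)))
  }
  objective <- function(t) {
    p <- c(exp(t[1]), exp(t[2]))
    v <- sum(w * (k - predict_fun(p, n))^2)
    if (!is.finite(v)) 1e12 else v
  }
  # Regression on the positive, below-1 points gives a natural start.
  pos <- k > 0 & k < 1
  x_reg <- if (kind == "EXP") n else log(n)
  starts <- list(c(0, log(1e-3)), c(log(2), log(0.1)))
  if (sum(pos) >= 2) {
    cf <- unname(stats::coef(stats::lm(log(k[pos]) ~ x_reg[pos])))
    if (is.finite(cf[2]) && cf[2] < 0) {
      starts <- c(list(c(cf[1], log(-cf[2]))), starts)
    }
  }
  best <- NULL
  for (t0 in starts) {
    opt <- stats::optim(t0, objective, method = "Nelder-Mead",
                        control = list(reltol = config$reltol,
                                       maxit = config$maxit))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  p <- unname(exp(best$par))
  .fit_result(kind, list(a = p[1], b = p[2]), best$value,
              best$convergence == 0, curve2)
}

#' Forecast correctness at a larger population size
#'
#' Evaluates a fitted correctness model at population size `n`. For the
#' Pitman-Yor (`"PYC"`) and entropy-only (`"ENT"`) models this is the
#' closed-form [expected_correctness()]; `"EXP"` and `"POL"` evaluate
#' their clipped decay laws; `"RND"` draws uniformly on `[0, kappa(n_t)]`
#' with a seed derived from the fit and `n`.
#'
#' @param fit A `"fit_result"` from [fit_pyc_mb()] or [fit_baseline()].
#' @param n Population size(s), `n >= 1`.
#' @return Forecast correctness in `[0, 1]`, vectorized over `n`.
#' @export
forecast <- function(fit, n) {
  stopifnot(inherits(fit, "fit_result"))
  .check_n(n)
  switch(fit$model,
    PYC = ,
    ENT = expected_correctness(n, info_params(fit$params$h, fit$params$gamma)),
    EXP = pmin(1, pmax(0, exp(log(fit$params$a) - fit$params$b * n))),
    POL = pmin(1, pmax(0, exp(log(fit$params$a) - fit$params$b * log(n)))),
    RND = withr::with_seed(fit$params$seed + as.integer(sum(n) %% 1e6), {
      stats::runif(length(n), 0, fit$params$kappa_max)
    }),
    stop("forecast: unknown model kind ", fit$model, call. = FALSE)
  )
}

#' Training gallery sizes evenly spaced in log scale
#'
#' The measurement design used throughout: `t` gallery sizes from 1 to
#' `n_max`, evenly spaced in log space, rounded to integers and
#' deduplicated (so the effective number of points can be smaller than `t`
#' for small `n_max`).
#'
#' @param n_max Largest training size.
#' @param t Nominal number of points.
#' @return Increasing integer vector of sizes.
#' @export
log_spaced_sizes <- function(n_max, t = 50L) {
  stopifnot(n_max >= 1)
  unique(round(exp(seq(0, log(n_max), length.out = t))))
}

#' Evaluate extrapolation accuracy on a set of collections
#'
#' The evaluation protocol for measurement-based forecasting: for each
#' collection (an [anonymity_counts()] gallery with known full-population
#' correctness `K/N`) and each sampling fraction `mu`, a training curve of
#' `t` points evenly spaced in log space from 1 to `mu * N` is measured by
#' exact subsampling, each requested model is fitted to it, and its
#' forecast at the full size `N` is compared with the empirical
#' correctness. Collections whose training curve ends outside
#' `(0.01, 0.99)` are excluded (near-degenerate curves carry no usable
#' signal). Reports per-forecast errors and RMSE/bias aggregates.
#'
#' @param collections Named list of [anonymity_counts()] objects.
#' @param mu Sampling fractions in `(0, 1]`.
#' @param models Character vector among `"PYC"`, `"ENT"`, `"EXP"`, `"POL"`,
#'   `"RND"`.
#' @param seed Integer seed (used by the `"RND"` baseline).
#' @param t_points Nominal training-curve length.
#' @param config An [mb_config()] shared by all model fits.
#' @return A list of class `"extrapolation_eval"` with `details` (one row
#'   per collection x mu x model) and `summary` (RMSE and mean bias per
#'   model x mu).
#' @export
evaluate_extrapolation <- function(collections, mu = c(0.01, 0.05, 0.1),
                                   models = c("PYC", "ENT", "EXP", "POL", "RND"),
                                   seed = 1L, t_points = 50L,
                                   config = mb_config()) {
  stopifnot(is.list(collections), length(collections) >= 1)
  models <- match.arg(models, c("PYC", "ENT", "EXP", "POL", "RND"),
                      several.ok = TRUE)
  if (is.null(names(collections))) {
    names(collections) <- sprintf("collection_%03d", seq_along(collections))
  }
  rows <- list()
  for (ci in seq_along(collections)) {
    cts <- collections[[ci]]
    truth <- empirical_correctness(cts)
    for (m_frac in mu) {
      n_t <- round(m_frac * cts$N)
      if (n_t < 2) {
        message(sprintf("skipping %s at mu = %g: training size %d < 2",
                        names(collections)[ci], m_frac, n_t))
        next
      }
      sizes <- log_spaced_sizes(n_t, t_points)
      curve <- subsampled_correctness_curve(cts, sizes)
      k_t <- curve$kappa[nrow(curve)]
      if (k_t <= 0.01 || k_t >= 0.99) next # inclusion filter
      for (mod in models) {
        fit <- switch(mod,
          PYC = fit_pyc_mb(curve, config),
          RND = fit_baseline(curve, "RND", config, seed = seed + ci),
          fit_baseline(curve, mod, config))
        fc <- forecast(fit, cts$N)
        rows[[length(rows) + 1]] <- data.frame(
          collection = names(collections)[ci], mu = m_frac, model = mod,
          n_train_max = n_t, n_forecast = cts$N,
          forecast = fc, truth = truth, error = fc - truth)
      }
    }
  }
  details <- do.call(rbind, rows)
  if (is.null(details)) {
    return(structure(list(details = data.frame(), summary = data.frame()),
                     class = "extrapolation_eval"))
  }
  summary <- do.call(rbind, lapply(split(details, list(details$model, details$mu),
                                         drop = TRUE), function(gr) {
    data.frame(model = gr$model[1], mu = gr$mu[1], n_collections = nrow(gr),
               rmse = sqrt(mean(gr$error^2)), bias = mean(gr$error))
  }))
  rownames(summary) <- NULL
  summary <- summary[order(summary$mu, summary$model), ]
  structure(list(details = details, summary = summary),
            class = "extrapolation_eval")
}

#' @export
print.extrapolation_eval <- function(x, ...) {
  cat("Extrapolation evaluation (RMSE and bias by model and sampling fraction):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
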