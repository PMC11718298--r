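# Measurement-based extrapolation: loss, model fits, forecasts, harness.

test_that("the log-weighted loss is zero at interpolation and quadratic in perturbations", {
  true <- info_params(4, 0.5)
  ns <- c(10, 100, 1000)
  curve <- correctness_curve(ns, expected_correctness(ns, true))
  expect_equal(pyc_mb_loss(true, curve), 0, tolerance = 1e-20)
  # single-point perturbation by eps changes the loss by log(n) * eps^2
  eps <- 0.01
  k2 <- expected_correctness(ns, true) - c(eps, 0, 0)
  curve2 <- correctness_curve(ns, k2)
  expect_equal(pyc_mb_loss(true, curve2), log(10) * eps^2, tolerance = 1e-12)
  # arbitrary hand case: loss is plain weighted arithmetic on model values
  cand <- info_params(5, 0.2)
  m <- expected_correctness(c(10, 100), cand)
  hand <- correctness_curve(c(10, 100), c(0.9, 0.5))
  expect_equal(pyc_mb_loss(cand, hand),
               log(10) * (0.9 - m[1])^2 + log(100) * (0.5 - m[2])^2)
  # n = 1 points carry no weight and are skipped with a warning
  with1 <- correctness_curve(c(1, 10, 100), c(1, 0.9, 0.5))
  expect_warning(l1 <- pyc_mb_loss(cand, with1), "n = 1")
  expect_equal(l1, pyc_mb_loss(cand, hand))
})

test_that("fit_pyc_mb recovers generating parameters from noiseless curves", {
  for (pars in list(c(10, 0.5), c(6, 0.1), c(18, 0.85))) {
    true <- info_params(pars[1], pars[2])
    ns <- log_spaced_sizes(1e6, 50)
    curve <- correctness_curve(ns, expected_correctness(ns, true))
    fit <- fit_pyc_mb(curve)
    expect_true(fit$converged)
    expect_lt(abs(fit$params$h - pars[1]) / pars[1], 0.01)
    expect_lt(abs(fit$params$gamma - pars[2]), 0.02)
  }
})

test_that("a degenerate all-ones curve pushes the entropy to its bound with a flag", {
  curve <- correctness_curve(c(10, 100, 1000), c(1, 1, 1))
  fit <- fit_pyc_mb(curve)
  expect_true(fit$flags$degenerate)
  expect_true(fit$flags$h_at_bound)
})

test_that("ENT is the gamma = 0 restriction and is dominated by the full model", {
  # data generated at gamma = 0: both fits agree
  true <- info_params(8, 0)
  ns <- log_spaced_sizes(1e5, 40)
  curve <- correctness_curve(ns, expected_correctness(ns, true))
  ent <- fit_baseline(curve, "ENT")
  pyc <- fit_pyc_mb(curve)
  expect_equal(ent$params$h, 8, tolerance = 1e-3)
  expect_lt(abs(forecast(ent, 1e7) - forecast(pyc, 1e7)), 1e-3)
  # nested-model dominance on arbitrary curves
  set.seed(31)
  for (r in 1:5) {
    ns2 <- sort(sample(2:5000, 12))
    kap <- sort(runif(12, 0.05, 0.99), decreasing = TRUE)
    crv <- correctness_curve(ns2, kap)
    expect_lte(fit_pyc_mb(crv)$loss, fit_baseline(crv, "ENT")$loss + 1e-8)
  }
})

test_that("EXP and POL recover exact decay-law parameters", {
  ns <- round(seq(10, 500, length.out = 30))
  pol_curve <- correctness_curve(ns, pmin(1, 2 * ns^-0.3))
  pol <- fit_baseline(pol_curve, "POL")
  expect_equal(pol$params$b, 0.3, tolerance = 1e-3)
  expect_equal(pol$params$a, 2, tolerance = 1e-2)
  exp_curve <- correctness_curve(ns, pmin(1, 0.9 * exp(-0.01 * ns)))
  exf <- fit_baseline(exp_curve, "EXP")
  expect_equal(exf$params$b, 0.01, tolerance = 1e-4)
  expect_equal(exf$params$a, 0.9, tolerance = 1e-2)
})

test_that("forecasts behave at the anchors and are monotone in population size", {
  true <- info_params(12, 0.4)
  ns <- log_spaced_sizes(1e5, 40)
  curve <- correctness_curve(ns, expected_correctness(ns, true))
  fits <- list(fit_pyc_mb(curve), fit_baseline(curve, "ENT"),
               fit_baseline(curve, "EXP"), fit_baseline(curve, "POL"))
  for (fit in fits) {
    grid <- c(1, 10, 1e3, 1e5, 1e7, 1e9)
    fc <- forecast(fit, grid)
    expect_true(all(diff(fc) <= 1e-12))
    expect_true(all(fc >= 0 & fc <= 1))
  }
  # PYC/ENT forecasts equal 1 at n = 1 exactly
  expect_equal(forecast(fits[[1]], 1), 1)
  expect_equal(forecast(fits[[2]], 1), 1)
  # at the largest training size the fit is within its residual of the data
  resid <- sqrt(fits[[1]]$loss / log(max(curve$n)))
  expect_lt(abs(forecast(fits[[1]], max(curve$n)) -
                curve$kappa[nrow(curve)]), resid + 1e-6)
  # RND draws are reproducible and bounded by the last training value
  rnd <- fit_baseline(curve, "RND", seed = 4)
  draws <- forecast(rnd, 1e6)
  expect_identical(draws, forecast(rnd, 1e6))
  expect_true(all(draws >= 0 & draws <= curve$kappa[nrow(curve)]))
})

test_that("log-spaced training designs are deduplicated and reach the endpoint", {
  s <- log_spaced_sizes(1000, 50)
  expect_equal(s[1], 1)
  expect_equal(s[length(s)], 1000)
  expect_true(all(diff(s) > 0))
  expect_lte(length(s), 50)
  expect_equal(log_spaced_sizes(2, 50), c(1, 2))
})

test_that("end-to-end harness: Pitman-Yor galleries are forecast within a few points", {
  # galleries from the prior itself, trained on a 10% subsample
  p <- py_params(0.4, 20)
  collections <- lapply(1:6, function(s) sample_crp(20000, p, seed = 100 + s))
  names(collections) <- paste0("crp_", 1:6)
  res <- suppressWarnings(
    evaluate_extrapolation(collections, mu = 0.1, models = "PYC", seed = 2))
  expect_equal(nrow(res$details), 6)
  expect_lt(median(abs(res$details$error)), 0.03)
  # at mu = 100% the curve ends at the truth: near-perfect self-fit
  res_full <- suppressWarnings(
    evaluate_extrapolation(collections[1:2], mu = 1, models = "PYC", seed = 2))
  expect_lt(res_full$summary$rmse, 0.02)
})

test_that("the harness applies the inclusion filter and skips tiny training sets", {
  # a gallery whose 10% training curve ends above 0.99 is excluded
  all_single <- anonymity_counts(rep(1, 1000))
  res <- suppressWarnings(
    evaluate_extrapolation(list(deg = all_single), mu = 0.1, models = "PYC"))
  expect_equal(nrow(res$details), 0)
  small <- anonymity_counts(c(5, 5))
  expect_message(
    res2 <- evaluate_extrapolation(list(s = small), mu = 0.01, models = "PYC"),
    "training size")
})
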