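# Exchangeable-partition likelihood, MAP fitting, and the samplers.

test_that("EPPF log-likelihood matches hand-computed partition probabilities", {
  # n = 2: two singletons w.p. (alpha + d)/(alpha + 1), one pair w.p. (1 - d)/(alpha + 1)
  expect_equal(eppf_log_likelihood(anonymity_counts(c(1, 1)), py_params(0.5, 1)),
               log(0.75))
  expect_equal(eppf_log_likelihood(anonymity_counts(2), py_params(0.5, 1)),
               log(0.25))
  # partition-level probabilities agree with the sequential-seating oracle
  for (pars in list(c(0.3, 0.7), c(0, 2), c(0.8, 0.1))) {
    blocks <- list(c(1L, 3L, 4L), 2L, c(5L, 6L))
    sizes <- lengths(blocks)
    expect_equal(eppf_log_likelihood(anonymity_counts(sizes),
                                     py_params(pars[1], pars[2])),
                 log(crp_partition_probability(blocks, pars[1], pars[2])),
                 tolerance = 1e-12)
  }
})

test_that("EPPF normalizes over all set partitions of n <= 4", {
  for (pars in list(c(0.5, 1), c(0.2, 5), c(0, 0.7), c(0.9, 0.05))) {
    for (n in 2:4) {
      parts <- enumerate_set_partitions(n)
      total <- sum(vapply(parts, function(p) {
        exp(eppf_log_likelihood(anonymity_counts(lengths(p)),
                                py_params(pars[1], pars[2])))
      }, numeric(1)))
      expect_equal(total, 1, tolerance = 1e-10)
    }
  }
})

test_that("EPPF decreases without bound, not erroring, as d nears its pole with multi-record sets", {
  lls <- vapply(c(0.9, 0.99, 0.9999, 0.9999999), function(d) {
    eppf_log_likelihood(anonymity_counts(c(3, 1)), py_params(d, 1))
  }, numeric(1))
  expect_true(all(diff(lls) < 0))
  expect_lt(lls[length(lls)], -15)
  # all-singleton partitions are unaffected by the d -> 1 pole
  expect_true(is.finite(
    eppf_log_likelihood(anonymity_counts(c(1, 1)), py_params(0.9999999, 1))))
})

test_that("fit_map recovers simulation parameters and is representation-invariant", {
  cts <- sample_crp(30000, py_params(0.5, 10), seed = 41)
  fit <- fit_map(cts)
  expect_true(fit$diagnostics$converged)
  expect_lt(abs(fit$py$d - 0.5), 0.07)
  # the information parameters round-trip the reported natural parameters
  expect_equal(py_from_info(fit$info)$d, fit$py$d, tolerance = 1e-6)
  # chunked multiset representation gives the identical fit
  tab <- cts$table
  split_rep <- anonymity_counts(
    c(rep(tab$size, tab$m), integer(0))) # re-expanded representation
  fit2 <- fit_map(split_rep)
  expect_equal(fit2$py$d, fit$py$d, tolerance = 1e-10)
  expect_equal(fit2$diagnostics$loglik, fit$diagnostics$loglik,
               tolerance = 1e-10)
})

test_that("degenerate partitions are flagged non-identifiable at the bounds", {
  all_single <- fit_map(anonymity_counts(rep(1, 500)))
  expect_false(all_single$diagnostics$identifiable)
  one_set <- fit_map(anonymity_counts(500))
  expect_false(one_set$diagnostics$identifiable)
  expect_lt(one_set$info$h, all_single$info$h)
  expect_error(fit_map(anonymity_counts(1)), "at least 2")
})

test_that("sample_crp reproduces the closed-form expectations (Monte-Carlo oracle)", {
  p <- py_params(0.5, 10)
  n <- 1000
  reps <- 300
  stats <- vapply(seq_len(reps), function(s) {
    cts <- sample_crp(n, p, seed = s)
    c(cts$K / n, empirical_uniqueness(cts), empirical_kanon_violations(cts, 5))
  }, numeric(3))
  for (i in 1:3) {
    target <- switch(i, expected_correctness(n, p), expected_uniqueness(n, p),
                     expected_kanon_violations(n, 5, p))
    se <- sd(stats[i, ]) / sqrt(reps)
    expect_lt(abs(mean(stats[i, ]) - target), 3 * se)
  }
  expect_equal(sample_crp(1, p, seed = 1)$table, data.frame(size = 1, m = 1))
  # identical seed, identical partition
  expect_identical(sample_crp(200, p, seed = 9)$table,
                   sample_crp(200, p, seed = 9)$table)
})

test_that("stick-breaking draws normalize and reproduce the expected entropy", {
  p <- py_params(0.5, 1)
  f <- sample_stick_breaking(p, seed = 2)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  hs <- vapply(1:500, function(s) {
    pi <- sample_stick_breaking(p, seed = s)
    -sum(pi * log(pi))
  }, numeric(1))
  se <- sd(hs) / sqrt(length(hs))
  expect_lt(abs(mean(hs) - (1 + 2 * log(2))), 3 * se)
  # small alpha, d = 0: the first stick carries almost all mass
  f0 <- sample_stick_breaking(py_params(0, 0.01), seed = 3)
  expect_gt(max(f0), 0.9)
})

test_that("CRP and stick-breaking induce the same distribution of set counts", {
  p <- py_params(0.3, 2)
  n <- 200
  k_crp <- vapply(1:400, function(s) sample_crp(n, p, seed = s)$K, numeric(1))
  k_sb <- vapply(1:400, function(s) {
    sample_gallery(sample_stick_breaking(p, seed = 1000 + s), n,
                   seed = 2000 + s)$K
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(k_crp, k_sb)$p.value), 0.01)
})

test_that("posterior predictive bands are sorted envelopes that cover same-model data", {
  p <- py_params(0.4, 5)
  bands <- posterior_predictive_bands(p, n = 300, reps = 120, seed = 6)
  expect_true(all(diff(bands$`q0.5`) <= 0)) # rank-size curves decrease
  expect_true(all(bands$`q0.975` >= bands$`q0.025`))
  # held-out draws from the same parameters fall inside the 95% envelope
  # at most ranks, most of the time
  coverage <- vapply(1:20, function(s) {
    cts <- sample_crp(300, p, seed = 5000 + s)
    rs <- sort(rep(cts$table$size, cts$table$m), decreasing = TRUE)
    rs <- c(rs, rep(0, nrow(bands) - length(rs)))[seq_len(nrow(bands))]
    mean(rs >= bands$`q0.025` & rs <= bands$`q0.975`)
  }, numeric(1))
  expect_gt(mean(coverage), 0.9)
  # reps = 1 degenerates to the single draw
  b1 <- posterior_predictive_bands(p, n = 50, reps = 1, seed = 1)
  expect_equal(b1$`q0.025`, b1$`q0.975`)
})

test_that("KL divergence matches the two-bin hand computation and self-consistency", {
  expect_equal(kl_divergence_bits(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log2(2) + 0.5 * log2(2 / 3), tolerance = 1e-12)
  expect_gte(kl_divergence_bits(c(0.3, 0.7), c(0.6, 0.4)), 0)
  expect_identical(kl_divergence_bits(c(1, 0), c(0, 1)), Inf)
  # predictive fitted at the true parameters: small divergence, large n
  p <- py_params(0.4, 5)
  emp <- sample_crp(5000, p, seed = 77)
  kl <- kl_ranksize(emp, p, reps = 60, seed = 78)
  expect_true(kl$support_overlap)
  expect_lt(kl$kl_bits, 1)
})
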