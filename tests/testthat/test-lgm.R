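test_that("benchmark specifications encode the published reference priors", {
  b1 <- benchmark_spec("benchmark1")
  expect_s3_class(b1$prior_alpha1, "uniform_dist")
  expect_equal(dist_support(b1$prior_alpha1), c(0, 100))
  expect_equal(dist_support(b1$prior_alpha2), c(-100, 100))

  b2 <- benchmark_spec("benchmark2")
  expect_s3_class(b2$prior_alpha1, "normal_dist")
  expect_equal(dist_var(b2$prior_alpha1), 1e8)
  expect_equal(dist_var(b2$prior_alpha2), 1e8)
  expect_equal(b2$prior_alpha1$mean, 0)

  # the two benchmarks differ only in the latent-mean priors
  expect_equal(b1[c("psi_df", "psi_scale", "theta_df", "theta_scale", "loadings")],
               b2[c("psi_df", "psi_scale", "theta_df", "theta_scale", "loadings")])
  expect_error(benchmark_spec("benchmark3"))
})

test_that("specification invariants are enforced", {
  expect_error(lgm_spec(dist_normal(0, 1e4), dist_normal(0, 1e4),
                        loadings = c(0.1, 0.5, 1)), "start at 0")
  expect_error(lgm_spec(dist_normal(0, 1e4), dist_normal(0, 1e4),
                        loadings = c(0, 0.5, 0.9)), "end at 1")
  expect_error(lgm_spec(dist_normal(0, 1e4), dist_normal(0, 1e4),
                        loadings = c(0, 1)), "3 waves")
  expect_error(lgm_spec(skew_normal_prior(0, 1), dist_normal(0, 1e4)),
               "dist_normal\\(\\) or dist_uniform\\(\\)")
})

test_that("prior draws under benchmark 1 respect the instrument scale", {
  b1 <- benchmark_spec("benchmark1")
  set.seed(8)
  d <- draw(b1$prior_alpha1, 5000)
  expect_true(all(d >= 0 & d <= 100))
  d2 <- draw(b1$prior_alpha2, 5000)
  expect_true(all(d2 >= -100 & d2 <= 100))
})

test_that("degenerate and malformed score data are rejected", {
  const <- data.frame(id = 1:5, t1 = 50, t2 = 50, t3 = 50)
  expect_error(fit_lgm(const, benchmark_spec("benchmark2")), "degenerate")
  two_waves <- data.frame(id = 1:5, t1 = runif(5, 0, 100), t2 = runif(5, 0, 100))
  expect_error(fit_lgm(two_waves, benchmark_spec("benchmark2")), "expected 3 waves")
})

test_that("subjects with missing waves are dropped listwise with a log message", {
  cfg <- truth_config(n = 40, clip = FALSE)
  d <- simulate_scores(cfg, seed = 31)
  d$t2[c(3, 7)] <- NA
  expect_message(fit <- fit_lgm_test(d, benchmark_spec("benchmark2"), seed = 2),
                 "listwise deletion: dropping 2")
  expect_equal(fit$n, 38)
})

test_that("the posterior concentrates on the mean line in the near-noise-free limit", {
  cfg <- truth_config(alpha1 = 30, alpha2 = -10, psi11 = 0.05, psi22 = 0.05,
                      corr = 0, theta = 0.05, n = 40, clip = FALSE)
  d <- simulate_scores(cfg, seed = 13)
  # near-degenerate variances mix slowly and may trip the convergence flag;
  # this test checks the posterior location, not the mixing speed
  fit <- suppressWarnings(fit_lgm_test(d, benchmark_spec("benchmark2"), seed = 3))
  s <- fit$summary
  expect_equal(s$mean[s$parameter == "alpha1"], 30, tolerance = 1)
  expect_equal(s$mean[s$parameter == "alpha2"], -10, tolerance = 1)
})

test_that("the reference posterior recovers synthetic truth and reports diagnostics", {
  cfg <- truth_config(n = 100, clip = FALSE)
  d <- simulate_scores(cfg, seed = 41)
  fit <- fit_lgm_test(d, benchmark_spec("benchmark2"), seed = 4)
  s <- fit$summary
  for (par in c("alpha1", "alpha2")) {
    truth <- if (par == "alpha1") cfg$alpha1 else cfg$alpha2
    row <- s[s$parameter == par, ]
    expect_lt(abs(row$mean - truth), 3 * sqrt(row$var))
    expect_true(is.finite(row$rhat))
    expect_gt(row$ess, 50)
  }
  expect_true(all(s$var > 0))
  expect_true(is.logical(fit$converged))

  # the moment-matched marginal reproduces the draws' moments
  marg <- posterior_marginal(fit, "alpha1")
  expect_equal(marg$mean, mean(fit$draws[, "alpha1"]))
  expect_equal(marg$sd, sd(fit$draws[, "alpha1"]))
  expect_error(posterior_marginal(fit, "nonexistent"), "no marginal")

  # seeded runs are reproducible
  fit2 <- fit_lgm_test(d, benchmark_spec("benchmark2"), seed = 4)
  expect_identical(fit$draws, fit2$draws)
})

test_that("results are insensitive to the exact middle loading", {
  # 3-month wave placed at 3/12 vs 2/11 of the follow-up
  cfg <- truth_config(n = 100, clip = FALSE)
  d <- simulate_scores(cfg, seed = 51)
  f1 <- fit_lgm_test(d, benchmark_spec("benchmark2"), seed = 5)
  f2 <- fit_lgm_test(d, benchmark_spec("benchmark2", loadings = c(0, 2 / 11, 1)),
                     seed = 5)
  for (par in c("alpha1", "alpha2")) {
    m1 <- f1$summary[f1$summary$parameter == par, ]
    m2 <- f2$summary[f2$summary$parameter == par, ]
    expect_lt(abs(m1$mean - m2$mean), 1.5 * sqrt(m1$var))
  }
})

test_that("split-Rhat detects both mixed and unmixed chains", {
  set.seed(6)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(good), 1.01)
  drifted <- cbind(rnorm(1000), rnorm(1000) + 3)
  expect_gt(split_rhat(drifted), 1.5)
  trending <- matrix(seq(0, 1, length.out = 1000) + rnorm(1000, 0, 0.05), 1000, 2)
  expect_gt(split_rhat(trending), 1.1)
})
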