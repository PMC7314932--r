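test_that("symmetric bounds produce a symmetric (normal) fit", {
  p <- fit_skew_normal(point = 30, lower = 20, upper = 40, coverage = 0.98)
  expect_equal(p$alpha, 0)
  expect_equal(p$xi, 30, tolerance = 1e-8)
  expect_equal(prob(p, 20), 0.01, tolerance = 1e-6)
  expect_equal(prob(p, 40), 0.99, tolerance = 1e-6)

  # symmetric case reduces to a normal whose 97.5% quantile sits at the bound
  p2 <- fit_skew_normal(point = 0, lower = -1, upper = 1, coverage = 0.95)
  expect_equal(p2$omega, 1 / qnorm(0.975), tolerance = 1e-6)
  expect_equal(p2$alpha, 0)
})

test_that("asymmetric bounds give a skewed fit hitting both quantiles and the mode", {
  p <- fit_skew_normal(point = 30, lower = 25, upper = 45, coverage = 0.98)
  expect_gt(p$alpha, 0)  # wider upper side: right-skewed
  expect_equal(prob(p, 25), 0.01, tolerance = 1e-4)
  expect_equal(prob(p, 45), 0.99, tolerance = 1e-4)
  expect_equal(skewnorm_mode(p$xi, p$omega, p$alpha), 30, tolerance = 1e-6)

  # mirrored judgment: opposite skew of equal magnitude
  m <- fit_skew_normal(point = -30, lower = -45, upper = -25, coverage = 0.98)
  expect_lt(m$alpha, 0)
  expect_equal(abs(m$alpha), abs(p$alpha), tolerance = 1e-3)
})

test_that("judgment validation rejects inconsistent inputs", {
  expect_error(bound_judgment(30, 40, 20), "strictly below")
  expect_error(bound_judgment(50, 20, 40), "strictly inside")
  expect_error(bound_judgment(30, 20, 40, coverage = 1), "in \\(0, 1\\)")
  # a point estimate essentially on top of a bound is not representable
  expect_error(fit_skew_normal(point = 20.01, lower = 20, upper = 60),
               "cannot represent")
})

test_that("widening the bounds at a fixed point never shrinks the scale", {
  base <- fit_skew_normal(point = 10, lower = 4, upper = 20)
  for (f in c(1.2, 1.5, 2, 4)) {
    wide <- fit_skew_normal(point = 10, lower = 10 - 6 * f, upper = 10 + 10 * f)
    expect_gt(wide$omega, base$omega)
  }
  # one-sided widening as well
  expect_gt(fit_skew_normal(point = 10, lower = 4, upper = 30)$omega, base$omega)
})

test_that("a warning flags substantial prior mass outside the instrument range", {
  expect_warning(
    fit_skew_normal(point = 5, lower = -20, upper = 30,
                    instrument_range = c(0, 100)),
    "outside \\[0, 100\\]")
  expect_silent(
    fit_skew_normal(point = 50, lower = 40, upper = 60,
                    instrument_range = c(0, 100)))
})

test_that("credible intervals invert the CDF at the requested central level", {
  expect_equal(credible_interval(dist_normal(0, 1), 0.95),
               c(-1, 1) * qnorm(0.975), tolerance = 1e-8)
  p <- fit_skew_normal(point = 30, lower = 25, upper = 45)
  for (lv in c(0.5, 0.9, 0.99)) {
    ci <- credible_interval(p, lv)
    expect_equal(prob(p, ci[2]) - prob(p, ci[1]), lv, tolerance = 1e-8)
  }
  expect_error(credible_interval(p, 1), "strictly inside")
  expect_error(credible_interval(p, 0), "strictly inside")
})

test_that("intercept-only bands are constant at the intercept credible interval", {
  p <- fit_skew_normal(point = 30, lower = 20, upper = 45)
  b <- band_for_trajectory(p, NULL, c(0, 0.25, 1), level = 0.95)
  ci <- credible_interval(p, 0.95)
  expect_true(all(b$lower == ci[1]))
  expect_true(all(b$upper == ci[2]))
})

test_that("two-parameter bands match closed-form propagation for normal priors", {
  ip <- dist_normal(30, 2)
  sp <- dist_normal(-10, 3)
  b <- band_for_trajectory(ip, sp, c(0, 1), level = 0.95, draws = 2e5, seed = 7)
  # at loading 0 the slope contributes nothing
  ci0 <- credible_interval(ip, 0.95)
  expect_equal(b$lower[1], ci0[1], tolerance = 0.1)
  expect_equal(b$upper[1], ci0[2], tolerance = 0.1)
  # at loading 1: I + S ~ N(20, 4 + 9)
  expect_equal(b$lower[2], 20 - qnorm(0.975) * sqrt(13), tolerance = 0.1)
  expect_equal(b$upper[2], 20 + qnorm(0.975) * sqrt(13), tolerance = 0.1)
  # seeded reproducibility
  b2 <- band_for_trajectory(ip, sp, c(0, 1), level = 0.95, draws = 2e5, seed = 7)
  expect_identical(b, b2)
})

test_that("band inputs are validated", {
  p <- dist_normal(0, 1)
  expect_error(band_for_trajectory(p, NULL, c(-0.1, 1)), "\\[0, 1\\]")
  expect_error(band_for_trajectory(p, p, c(0, 1), level = 1.2), "\\(0, 1\\)")
})
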