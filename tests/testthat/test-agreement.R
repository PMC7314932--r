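test_that("KL divergence matches hand-derived closed forms", {
  # identical distributions lose no information
  p <- dist_normal(3, 2)
  expect_lt(kl_divergence(p, p), 1e-10)
  sn <- fit_skew_normal(point = 20, lower = 10, upper = 45)
  expect_lt(kl_divergence(sn, sn, method = "quadrature"), 1e-8)

  # unit-variance normals a mean apart: (mu1-mu2)^2 / 2
  expect_equal(kl_divergence(dist_normal(0, 1), dist_normal(1, 1)), 0.5,
               tolerance = 1e-12)
  expect_equal(kl_divergence(dist_normal(0, 1), dist_normal(1, 1),
                             method = "quadrature"), 0.5, tolerance = 1e-8)

  # normal against the instrument-scale uniform: log-width minus entropy
  v <- kl_divergence(dist_normal(22.7, sqrt(1.3)), dist_uniform(0, 100))
  expect_equal(v, log(100) - 0.5 * log(2 * pi * exp(1) * 1.3), tolerance = 1e-12)
})

test_that("KL is asymmetric between unequal-variance normals", {
  a <- dist_normal(0, 1)
  b <- dist_normal(0, 2)  # variance 4
  kl_ab <- kl_divergence(a, b)
  kl_ba <- kl_divergence(b, a)
  expect_equal(kl_ab, log(2) - 3 / 8, tolerance = 1e-12)
  expect_equal(kl_ba, 3 / 2 - log(2), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(kl_ab, kl_ba)))
  # quadrature agrees in both directions
  expect_equal(kl_divergence(a, b, method = "quadrature"), kl_ab, tolerance = 1e-8)
  expect_equal(kl_divergence(b, a, method = "quadrature"), kl_ba, tolerance = 1e-8)
})

test_that("a prior with no support where the posterior has mass diverges", {
  expect_identical(kl_divergence(dist_normal(50, 10), dist_uniform(0, 60)), Inf)
  expect_identical(kl_divergence(dist_uniform(0, 10), dist_uniform(2, 10)), Inf)
  # nested uniforms: log width ratio
  expect_equal(kl_divergence(dist_uniform(2, 4), dist_uniform(0, 10)),
               log(10 / 2), tolerance = 1e-12)
})

test_that("quadrature agrees with closed forms across a grid of pairs", {
  cases <- expand.grid(m1 = c(-5, 0, 10), s1 = c(0.5, 1, 3),
                       m2 = c(-2, 4), s2 = c(1, 8))
  for (i in seq_len(nrow(cases))) {
    p <- dist_normal(cases$m1[i], cases$s1[i])
    q <- dist_normal(cases$m2[i], cases$s2[i])
    expect_equal(kl_divergence(p, q, method = "quadrature"),
                 kl_divergence(p, q, method = "closed"), tolerance = 1e-6)
  }
  # normal vs uniform with the posterior well inside the support
  for (m in c(20, 40, 60)) for (s in c(1, 2, 4)) {
    p <- dist_normal(m, s)
    q <- dist_uniform(0, 100)
    expect_equal(kl_divergence(p, q, method = "quadrature"),
                 kl_divergence(p, q, method = "closed"), tolerance = 1e-6)
  }
})

test_that("KL works for skew-normal and mixture priors and stays non-negative", {
  post <- dist_normal(22.7, sqrt(1.3))
  sn <- fit_skew_normal(point = 25, lower = 15, upper = 50)
  mix <- pool(list(sn, fit_skew_normal(point = 20, lower = 5, upper = 30)))
  for (q in list(sn, mix)) {
    v <- kl_divergence(post, q)
    expect_true(is.finite(v))
    expect_gte(v, 0)
  }
})

test_that("shrinking a mislocated prior strictly increases the divergence", {
  post <- dist_normal(22.7, sqrt(1.3))
  sds <- c(8, 4, 2, 1, 0.5, 0.1)   # ever more overconfident, same wrong centre
  kls <- vapply(sds, function(s) kl_divergence(post, dist_normal(30, s)),
                numeric(1))
  expect_true(all(diff(kls) > 0))
})

test_that("the agreement table ranks candidate priors against the reference", {
  post <- list(intercept = dist_normal(22.7, sqrt(1.3)),
               slope = dist_normal(-14.6, sqrt(1.9)))
  priors <- list(
    "Self" = list(intercept = post$intercept, slope = post$slope),
    "Benchmark 1" = list(intercept = dist_uniform(0, 100),
                         slope = dist_uniform(-100, 100)),
    "Benchmark 2" = list(intercept = dist_normal(0, 1e4),
                         slope = dist_normal(0, 1e4)))
  tab <- build_agreement_table(post, priors)
  expect_s3_class(tab, "agreement_table")
  expect_equal(tab$label, names(priors))       # input order preserved
  expect_equal(tab$kl_intercept[1], 0)
  expect_equal(tab$kl_slope[1], 0)
  expect_true(all(tab$kl_intercept >= 0 & tab$kl_slope >= 0))

  # rows are independent: a subset table reproduces the same values
  sub <- build_agreement_table(post, priors["Benchmark 1"])
  expect_equal(sub$kl_intercept, tab$kl_intercept[2])
  expect_equal(sub$kl_slope, tab$kl_slope[2])

  expect_error(build_agreement_table(list(intercept = post$intercept), priors),
               "intercept.*slope")
})
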