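# Shared fixture builders; everything is generated in code at test time.

# a randomized but representable bound judgment: the point estimate sits at
# relative position `pos` between the bounds (0.5 = symmetric)
random_judgment <- function(pos = stats::runif(1, 0.15, 0.85),
                            coverage = sample(c(0.90, 0.95, 0.98, 0.99), 1)) {
  point <- stats::runif(1, -50, 80)
  width <- stats::runif(1, 2, 40)
  bound_judgment(point, point - pos * width, point + (1 - pos) * width,
                 coverage)
}

# a small cohort of synthetic experts split 7/7 into the two groups
make_expert_panel <- function(truth = truth_config(), seed = 100) {
  lapply(1:14, function(k) {
    grp <- if (k <= 7) "psychologist-group" else "nurse-group"
    simulate_expert(truth,
                    expert_profile(group = grp, label = sprintf("expert-%02d", k)),
                    seed = seed + k)
  })
}

# reduced but reliable MCMC settings for tests
fit_lgm_test <- function(data, spec, seed = 1) {
  fit_lgm(data, spec, chains = 2, warmup = 1000, iter = 2000, seed = seed)
}
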