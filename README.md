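# elicitlgm

Expert elicitation and prior–data agreement for latent growth curve models.

## What this is for

Longitudinal studies of rare clinical outcomes — the motivating case is
posttraumatic stress symptoms (PTSS) in children after severe burn injuries,
scored 0–100 at roughly 1, 3 and 12 months post-event — often cannot recruit
enough subjects to estimate a latent growth curve model (LGM) comfortably.
Clinical experts are an alternative information source. `elicitlgm` is the
computational engine for a structured, multi-parameter elicitation of expert
beliefs about the LGM's group parameters, and for asking, numerically, *how
much the experts and the data disagree*.

The LGM is linear: subject $i$ at wave $t$ scores
$y_{it} = I_i + \lambda_t S_i + \varepsilon_{it}$, with latent
$(I_i, S_i) \sim N_2((\alpha_1, \alpha_2), \Psi)$ and
$\varepsilon_{it} \sim N(0, \theta)$; slope loadings run from 0 (first wave)
to 1 (12 months), so $\alpha_2$ is the expected change over one year.

The package covers the full pipeline:

* **Five-step elicitation** — reduce ten fictive individual trajectories to
  point estimates for $\alpha_1$ and $\alpha_2$ (`derive_point_estimates`),
  feed back the implied average trajectory, then turn each point estimate
  plus stated lower/upper bounds (1st/99th percentiles by default) into a
  skew-normal prior whose mode is the point estimate and whose CDF hits both
  bounds (`fit_skew_normal`), with credible-interval and trajectory-band
  feedback (`credible_interval`, `band_for_trajectory`).
* **Opinion pooling** — equal-weight linear pooling of expert priors into
  group mixtures (`pool`, `pool_judgments`).
* **Reference posterior** — Bayesian estimation of the LGM via JAGS under
  uninformative benchmark priors: instrument-scale uniforms ($U(0,100)$,
  $U(-100,100)$; benchmark 1) or $N(0, 10^8)$ defaults (benchmark 2), with
  half-$t(3,0,196)$ variance priors and $U(-1,1)$ on the latent correlation
  (`benchmark_spec`, `fit_lgm`).
* **Prior–data (dis)agreement** — Kullback–Leibler divergence, in nats, from
  the reference posterior to each candidate prior
  (`kl_divergence`, `build_agreement_table`): confident-and-wrong priors are
  penalized hardest, which makes the table an overconfidence diagnostic.
* **Synthetic data** — seeded generators for score datasets from a known
  truth and for synthetic experts with controllable bias and overconfidence
  (`simulate_scores`, `simulate_expert`), so the whole pipeline runs without
  any external data.

The skew-normal distribution functions (`dskewnorm`, `pskewnorm`,
`qskewnorm`, `rskewnorm`) are implemented in-package via Owen's T function.

## Worked example

One expert, one synthetic dataset, one agreement table:

```r
library(elicitlgm)

# Steps 1-2: ten fictive individual trajectories -> point estimates
tr <- data.frame(start = c(35, 20, 28, 45, 18, 30, 25, 38, 22, 29),
                 end   = c(12,  8, 15, 30,  5, 14, 10, 26,  9, 13))
est <- derive_point_estimates(tr)
#> Point estimates: intercept = 29, slope = -14.8 (per year)

# Steps 3-4: bounds -> skew-normal priors (asymmetric bounds => skewed fit)
prior_i <- fit_skew_normal(point = est$intercept, lower = 22, upper = 40)
prior_s <- fit_skew_normal(point = est$slope, lower = -25, upper = -5)
prior_i
#> Skew-normal prior: xi = 26.1, omega = 5.396, alpha = 1.836
round(credible_interval(prior_i, 0.95), 1)
#> [1] 23.1 38.2

# Reference posterior on (synthetic) data under benchmark-2 priors
scores <- simulate_scores(truth_config(n = 100, clip = FALSE), seed = 1)
fit <- fit_lgm(scores, benchmark_spec("benchmark2"),
               chains = 2, warmup = 1000, iter = 2000, seed = 1)
fit
#> LGM posterior (n = 100 subjects; 2 chains x 2000 iterations; converged)
#>   parameter     mean       var   rhat    ess
#> 1    alpha1  24.0518    1.0101 1.0008 1799.8
#> 2    alpha2 -15.8959    2.2425 0.9999 1642.6
#> ...

# How much information is lost approximating the posterior by each prior?
build_agreement_table(fit, list(
  "this expert" = list(intercept = prior_i, slope = prior_s),
  "Benchmark 1" = list(intercept = dist_uniform(0, 100),
                       slope = dist_uniform(-100, 100)),
  "Benchmark 2" = list(intercept = dist_normal(0, 1e4),
                       slope = dist_normal(0, 1e4))))
#> Prior-data (dis)agreement, KL(posterior || prior) in nats
#>   reference posterior: intercept N(24.05, var 1.01), slope N(-15.9, var 2.243)
#>        label kl_intercept kl_slope
#>  this expert         2.04     0.65
#>  Benchmark 1         3.18     3.48
#>  Benchmark 2         8.71     8.31
```

Reading the table: this (well-calibrated) expert loses less information than
either benchmark — their beliefs approximate the data better than flat
ignorance does. The instrument-aware uniforms (benchmark 1) lose ~3.2–3.5
nats; the $N(0, 10^8)$ defaults pay ~5 extra nats for spreading mass over an
astronomically larger range.

A thin command-line wrapper over the same functions ships in
`inst/cli/elicit.R` (subcommands `simulate`, `derive`, `fit-prior`, `pool`,
`fit-lgm`, `agreement`), e.g.

```sh
Rscript inst/cli/elicit.R simulate --what scores --n 100 --seed 1 --out scores.csv
Rscript inst/cli/elicit.R fit-lgm --data scores.csv --benchmark 2 --seed 1 --out posterior.json
```

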