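---
title: "Eliciting growth-model priors and measuring prior-data agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eliciting growth-model priors and measuring prior-data agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elicitlgm)
```

## The problem

Longitudinal studies of rare clinical events — here, posttraumatic stress
symptoms (PTSS) in children after severe burn injuries — rarely reach the
sample sizes that latent growth curve models (LGMs) would like. Clinical
experts are an alternative information source: nurses and psychologists who
see these children daily hold beliefs about how symptoms start and evolve.
`elicitlgm` implements the computational side of a structured, multi-parameter
elicitation of those beliefs, their aggregation across experts, and a
numerical comparison of beliefs against questionnaire data.

The pipeline has four stages:

1. **Elicitation** (`derive_point_estimates`, `fit_skew_normal`): turn an
   expert's drawn trajectories and stated bounds into skew-normal priors for
   the growth model's mean intercept and mean slope.
2. **Pooling** (`pool`): combine experts into equal-weight mixture priors.
3. **Reference posterior** (`fit_lgm`): estimate the LGM on observed score
   data under deliberately uninformative benchmark priors, as a stand-in for
   "what the data say".
4. **Agreement** (`kl_divergence`, `build_agreement_table`): rank every
   candidate prior by the Kullback-Leibler divergence from the reference
   posterior to it.

## The growth model

Scores are measured on a standardized 0-100 scale (clinical cutoff 42) at
three occasions: about 1 month, 3 months, and 12 months after the event.
For subject $i$ at wave $t$,

$$y_{it} = I_i + \lambda_t S_i + \varepsilon_{it}, \qquad
 (I_i, S_i) \sim N_2\!\left(
   \begin{pmatrix}\alpha_1\\\alpha_2\end{pmatrix},
   \begin{pmatrix}\psi_{11} & \psi_{21}\\ \psi_{21} & \psi_{22}\end{pmatrix}
 \right), \qquad \varepsilon_{it} \sim N(0, \theta).$$

The slope loadings are fixed with $\lambda_1 = 0$ and $\lambda_T = 1$, so
$\alpha_2$ is the expected change over the whole follow-up year — a unit
experts can reason about. The loading of the 3-month wave is not pinned down
by this convention; we default to $\lambda_2 = 0.25$ (3/12 of a year,
linear-in-time placement) and expose it as a configuration. A regression
test checks that moving it to $2/11$ (linear placement measured from the
1-month baseline) shifts the latent-mean posteriors by well under one
posterior SD, so downstream conclusions do not hinge on this choice.

Residual variance $\theta$ is shared across waves; $\psi_{21}$ is
parameterized through a correlation, $\psi_{21} = \rho\sqrt{\psi_{11}\psi_{22}}$,
because its $U(-1, 1)$ reference prior has the support of a correlation, not
of a covariance.

## Step-by-step elicitation

**Steps 1-2 (indirect).** The expert sketches ten fictive but representative
individual score paths, each reduced to its value at the first time point
and at 12 months. The point estimate for $\alpha_1$ is the mean of the start
values; for $\alpha_2$ the mean of the individual changes. Feedback is the
implied average trajectory (`average_trajectory`). Only these two means are
extracted: the model is linear, so the drawn paths carry no further
information about the group means. Fewer than three trajectories triggers a
warning (the average is weakly supported) but not an error, and the
accept/revise loop is stateless — the caller simply replaces the trajectory
set and re-derives.

**Steps 3-4 (direct).** The expert states a reasonable lower and upper bound
for each point estimate. Two interpretation choices are deliberate:

* *Bounds span 98% central mass* (the 1st and 99th percentiles), configurable
  via `coverage`. "Reasonable bounds" have no canonical probability; we pin
  them near-but-not-at certainty, consistent with reporting 99% intervals
  when discussing expert overconfidence.
* *The point estimate is the mode*, not the mean or median. Feedback is a
  density plot, and the visually dominant feature an expert anchors on is
  the peak.

**The skew-normal representation.** Each belief becomes a skew-normal
distribution with density $f(x) = (2/\omega)\,\phi(z)\,\Phi(\alpha z)$,
$z = (x-\xi)/\omega$: symmetric bounds give $\alpha = 0$ (an ordinary
normal), asymmetric bounds tilt the density toward the wider side without
needing a second shape parameter. The direct location-scale-shape
parameterization is used throughout; serialized priors store
$(\xi, \omega, \alpha)$ verbatim.

**Fitting.** The fit must satisfy three conditions: CDF(lower) $= 0.01$,
CDF(upper) $= 0.99$, mode $=$ point. Rather than minimizing the three
residuals over $(\xi, \omega, \alpha)$ jointly — a formulation whose narrow
curved valley stalls general-purpose optimizers well short of the $10^{-4}$
probability tolerance — we exploit a reduction: with the mode pinned at the
point estimate, the mode's relative position between the two bound
quantiles of a *standard* skew normal depends only on $\alpha$ and is
strictly monotone in it. Solving that one-dimensional root problem gives
$\alpha$ to near machine precision; $\omega$ is then the bound width divided
by the standardized inter-quantile width, and $\xi$ follows from the mode.
Symmetric judgments short-circuit to $\alpha = 0$ exactly. Judgments more
asymmetric than any skew normal can express (at 98% coverage, the point
estimate closer than about 3% of the bound width to either bound) are
rejected with an informative error rather than fitted badly.

Priors are never truncated to the 0-100 instrument scale — published pooled
densities are unbounded — but `fit_skew_normal(..., instrument_range = c(0, 100))`
warns when more than 1% of the fitted mass falls outside it.

**Step 5** is acceptance; computationally it is the serialization surface
(`write_judgments`, `write_prior`).

## Pooling

Group priors are *linear* (arithmetic) opinion pools with equal weights:
the mixture density is the average of the component densities. Linear
pooling is the only pooling rule that preserves the multimodality visible
when experts genuinely disagree; logarithmic pooling would manufacture a
consensus none of the experts holds. Equal weights reflect a panel selected
for diversity rather than scored on calibration questions —
performance-based weighting (Cooke's classical model) is an explicit
extension point, not implemented. Group membership is metadata on the
judgment; pooling never infers it.

## The reference posterior

Two benchmark prior sets for the latent means define "uninformative":

* **Benchmark 1** encodes only the instrument: $\alpha_1 \sim U(0, 100)$,
  $\alpha_2 \sim U(-100, 100)$.
* **Benchmark 2** reflects common default practice: $\alpha_1, \alpha_2 \sim
  N(0, 10^8)$ (variance $10^8$).

Both share half-$t(3, 0, 196)$ priors on $\psi_{11}$, $\psi_{22}$, $\theta$
and $U(-1,1)$ on the latent correlation. The half-$t$ scale is applied on
the variance scale exactly as printed; the alternative reading (scale 14 on
the SD scale, $14^2 = 196$) is a flagged ambiguity — under vague mean priors
and $n \ge 100$ the data dominate these variance priors either way.

Sampling is Gibbs via JAGS (`rjags`), 4 chains of 2,000 warmup + 2,000
retained draws by default, with chain seeds and overdispersed data-based
initial values derived deterministically from one root seed. Convergence is
summarized by split-$\hat R$ (computed in-package, each chain split in half)
and effective sample size; a fit whose latent-mean $\hat R$ exceeds 1.01 is
flagged and warned about, never silently returned. Marginal posteriors are
reported as moment-matched normal approximations — the same approximation
under which the published divergence table is reproduced — with raw draws
retained for interval computations. The package's tests run reduced chains
(2 chains, 1,000 + 2,000) on $n = 100$ synthetic subjects, sizes at which
the diagnostics are comfortably clean for this three-wave model.

*Stable estimation.* With $n \ge 100$ subjects the two benchmarks yield
latent-mean posteriors differing by a small fraction of a posterior SD
(asserted at $< 0.25$ SD across 20 replications): the data overwhelm any
reasonable vague prior, which is what licenses calling either posterior
"the" reference.

## Prior-data (dis)agreement

Agreement is quantified as $KL(\text{posterior} \,\|\, \text{prior})$ in
nats — the information lost when the reference posterior is approximated by
the candidate prior. The direction matters: it penalizes priors that are
confident *and wrong* much harder than priors that are merely vague, which
is exactly the asymmetry an overconfidence diagnostic needs. Shrinking a
mislocated prior's spread strictly increases its divergence (a tested
property): stating narrow bounds is only rewarded when they are in the
right place.

Closed forms are used for normal-normal and normal-uniform pairs; all other
pairs (skew normals, mixtures) go through adaptive quadrature on the log
density scale over the posterior's effective support (mean $\pm$ 12 SD,
clipped to the prior's support), with absolute tolerance well below
$10^{-8}$ and a documented $+\infty$ when the prior has no support where
the posterior has mass above $10^{-12}$. Quadrature and closed forms agree
to $10^{-6}$ nats on a randomized grid — the oracle check for the numeric
path.

Reproducing the published benchmark rows fixes two conventions empirically:
divergences are in nats (bits would be off by $\times 1.44$), and the
printed posterior approximations $N(22.7, 1.3)$ and $N(-14.6, 1.9)$ read
their second parameter as a **variance** (the SD reading misses the
published values by far more than the table's rounding). The ~0.02-nat gaps
that remain (3.055 computed vs 3.04 printed) are consistent with the true
reference posterior being only approximately normal; the package asserts
agreement at $\pm 0.05$ nats and does not chase the rounding.

## What the synthetic-data generator emulates

`truth_config()` defaults describe a cohort resembling the motivating one:
$\alpha_1 = 22.7$, $\alpha_2 = -14.6$ (so synthetic runs are visually
comparable to the published posteriors), $\psi_{11} = 85$,
$\psi_{22} = 110$, $\rho = -0.3$, $\theta = 45$, $n = 100$. The variance
components were chosen once so that the implied posterior variances of the
latent means at $n = 100$ land near the published approximations
($\approx 1.3$ for the intercept, $\approx 1.9$ for the slope); they are
not fitted to any data.

Two features of real data are deliberately simplified:

* **Boundary behavior.** Real scores cannot leave 0-100. Clipping is the
  generator default (the clipped fraction is logged), but clipping is
  *censoring*: under the default truth about a quarter of 12-month scores
  sit at 0, which biases a naive LGM fit of clipped data by roughly +2
  score points on the slope. Parameter-recovery tests therefore run with
  `clip = FALSE` — they test the sampler against its own model, not the
  model against censored data. A passing recovery test says nothing about
  boundary-induced bias in real scores; an honest analysis of heavily
  censored data would need a censored-likelihood model, which is out of
  scope here.
* **Experts.** A synthetic expert draws its ten fictive trajectories from
  the truth's individual-level distribution with the latent means shifted
  by a location `bias`, and states bounds centred on its own derived point
  estimates with half-width $z_{0.99}\sqrt{\psi/10}/\kappa$ — the honest
  98% sampling spread of a ten-individual mean, divided by the
  overconfidence factor $\kappa$. This makes $\kappa = 1$ experts
  calibrated by construction and $\kappa = 10$ experts exactly ten times
  too narrow, a clean dial for overconfidence experiments; real experts'
  biases are of course not this well behaved.

## Numerical choices

* Skew-normal CDF via Owen's T function (adaptive quadrature, ~$10^{-13}$
  relative tolerance); quantiles by safeguarded root finding to $10^{-13}$;
  the standard skew-normal mode by golden-section maximization to
  $10^{-12}$ (no closed form exists).
* Random skew-normal draws use the $\delta|u_0| + \sqrt{1-\delta^2}u_1$
  construction; Monte Carlo services (trajectory bands) use $10^5$ seeded
  draws by default and restore the caller's RNG state.
* Mixture quantiles invert the mixture CDF by root finding bracketed by the
  extreme component quantiles; ties and identical components are exact
  pass-throughs of the component distribution.
* Degenerate inputs error early with named fields: empty trajectory sets,
  bounds out of order, points outside bounds, constant score matrices,
  levels outside $(0,1)$.

## Limitations

* Only linear individual trajectories; experts who think in nonlinear
  recovery shapes are forced through a linear reduction.
* One shared residual variance across waves (a per-wave option exists in
  the model string but is not exposed); no covariates, no missing-data
  model beyond listwise deletion (which is logged).
* The skew normal cannot represent extreme point-near-bound asymmetry;
  such judgments are rejected, not approximated.
* KL is the only divergence offered; it is not a metric and the ranking it
  induces is direction-specific by design.
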