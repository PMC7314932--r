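Package: elicitlgm
Title: Expert Elicitation and Prior-Data Agreement for Latent Growth
    Curve Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the multi-parameter Five-Step elicitation of expert
    beliefs about the parameters of a linear latent growth curve model
    (LGM): indirect elicitation of fictive individual trajectories,
    reduction to point estimates for the group mean intercept and slope,
    representation of each belief as a skew-normal distribution fitted
    from a point estimate and reasonable lower/upper bounds, equal-weight
    linear opinion pooling into group mixture priors, Bayesian estimation
    of the LGM reference posterior under uninformative benchmark priors
    (via 'rjags'), and quantification of prior-data (dis)agreement by
    Kullback-Leibler divergence from the reference posterior to each
    candidate prior. Includes a synthetic-data generator for longitudinal
    bounded-scale scores and for expert judgments with controllable bias
    and overconfidence, so the whole pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
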