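#' Configure a true data-generating latent growth model
#'
#' The ground truth used by the synthetic-data generator: latent intercept
#' and slope means, (co)variance structure, residual noise and design.
#' Defaults mirror a cohort of about one hundred pediatric burn patients
#' whose posttraumatic stress scores (0--100 scale) start around 23 on
#' average and drop by about 15 points over the first year, with
#' substantial individual spread.
#'
#' @param alpha1,alpha2 true latent means: intercept (score units) and
#'   slope (score units per year).
#' @param psi11,psi22 latent intercept and slope variances, > 0.
#' @param corr latent intercept--slope correlation, in (-1, 1).
#' @param theta residual variance per wave, > 0.
#' @param n number of subjects.
#' @param loadings slope loadings per wave (first 0, last 1).
#' @param clip if `TRUE` (default), simulated scores are clipped to the
#'   instrument range \[0, 100\]; the clipped fraction is recorded.
#' @return an object of class `"truth_config"`.
#' @export
truth_config <- function(alpha1 = 22.7, alpha2 = -14.6,
                         psi11 = 85, psi22 = 110, corr = -0.3,
                         theta = 45, n = 100,
                         loadings = c(0, 0.25, 1), clip = TRUE) {
  stopifnot(psi11 > 0, psi22 > 0, theta > 0, n >= 1,
            corr > -1, corr < 1,
            loadings[1] == 0, loadings[length(loadings)] == 1)
  structure(list(alpha1 = alpha1, alpha2 = alpha2,
                 psi11 = psi11, psi22 = psi22, corr = corr,
                 theta = theta, n = as.integer(n),
                 loadings = loadings, clip = isTRUE(clip)),
            class = "truth_config")
}

# draw n latent (intercept, slope) pairs from the truth's bivariate normal
draw_latents <- function(cfg, n, bias1 = 0, bias2 = 0) {
  cov12 <- cfg$corr * sqrt(cfg$psi11 * cfg$psi22)
  sigma <- matrix(c(cfg$psi11, cov12, cov12, cfg$psi22), 2)
  ch <- chol(sigma)
  z <- matrix(stats::rnorm(n * 2), n, 2) %*% ch
  cbind(z[, 1] + cfg$alpha1 + bias1, z[, 2] + cfg$alpha2 + bias2)
}

#' Simulate a longitudinal score dataset from a true LGM
#'
#' Each subject gets a latent (intercept, slope) pair from the bivariate
#' normal population distribution; observed scores are the latent line
#' evaluated at the slope loadings plus residual noise. With clipping on,
#' scores are truncated to \[0, 100\] and the affected fraction is stored
#' in the `clip_fraction` attribute (and logged).
#'
#' @param cfg a [truth_config()].
#' @param seed integer seed; identical `cfg` and `seed` reproduce the
#'   dataset exactly.
#' @return a data.frame with column `id` and one score column per wave
#'   (`t1`, `t2`, ...), with attributes `clip_fraction` and `cutoff` (the
#'   clinical cutoff 42 of the standardized instrument, carried as
#'   metadata).
#' @examples
#' head(simulate_scores(truth_config(n = 5), seed = 1))
#' @export
simulate_scores <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "truth_config"))
  with_seed(seed, {
    eta <- draw_latents(cfg, cfg$n)
    nt <- length(cfg$loadings)
    y <- eta[, 1] %o% rep(1, nt) + eta[, 2] %o% cfg$loadings +
      matrix(stats::rnorm(cfg$n * nt, 0, sqrt(cfg$theta)), cfg$n, nt)
    clip_frac <- 0
    if (cfg$clip) {
      clip_frac <- mean(y < 0 | y > 100)
      if (clip_frac > 0)
        message(sprintf("clipped %.2f%% of simulated scores to [0, 100]",
                        100 * clip_frac))
      y <- pmin(pmax(y, 0), 100)
    }
    out <- data.frame(id = seq_len(cfg$n), y)
    names(out) <- c("id", paste0("t", seq_len(nt)))
    attr(out, "clip_fraction") <- clip_frac
    attr(out, "cutoff") <- 42
    out
  })
}

#' Describe a synthetic expert
#'
#' Controls how a simulated expert deviates from the truth: a location
#' bias shifts the latent means the expert believes in, and an
#' overconfidence factor `kappa` divides the honest width of the stated
#' bounds (`kappa = 1` is calibrated, `kappa = 10` severely overconfident
#' -- bounds ten times too narrow).
#'
#' @param bias_intercept,bias_slope additive bias (score units) applied to
#'   the expert's belief about the latent means.
#' @param kappa overconfidence factor, > 0.
#' @param group group label for the resulting judgment.
#' @param label expert id label.
#' @return an object of class `"expert_profile"`.
#' @export
expert_profile <- function(bias_intercept = 0, bias_slope = 0, kappa = 1,
                           group = c("other", "psychologist-group",
                                     "nurse-group"),
                           label = "synthetic-expert") {
  group <- match.arg(group)
  stopifnot(is.finite(kappa), kappa > 0)
  structure(list(bias_intercept = bias_intercept, bias_slope = bias_slope,
                 kappa = kappa, group = group, label = label),
            class = "expert_profile")
}

#' Simulate one expert's complete elicitation record
#'
#' Emulates the Five-Step procedure for a synthetic expert: draws fictive
#' individual trajectories from the truth's individual-level distribution
#' (with the latent means shifted by the profile's bias), derives the
#' point estimates, states bounds centred on those point estimates with an
#' honest width (the sampling spread of a mean of `n_traj` individuals)
#' divided by the overconfidence factor, and fits the skew-normal priors.
#'
#' @param truth a [truth_config()].
#' @param profile an [expert_profile()].
#' @param seed integer seed.
#' @param n_traj number of fictive trajectories (default 10).
#' @param coverage central mass the stated bounds span (default 0.98).
#' @return an [expert_judgment()].
#' @export
simulate_expert <- function(truth, profile, seed = 1, n_traj = 10,
                            coverage = 0.98) {
  stopifnot(inherits(truth, "truth_config"), inherits(profile, "expert_profile"))
  with_seed(seed, {
    eta <- draw_latents(truth, n_traj, profile$bias_intercept,
                        profile$bias_slope)
    start <- pmin(pmax(eta[, 1], 0), 100)
    end <- pmin(pmax(eta[, 1] + eta[, 2], 0), 100)
    traj <- data.frame(subject_label = paste0("fictive-", seq_len(n_traj)),
                       start = start, end = end)
    est <- derive_point_estimates(traj)

    z <- stats::qnorm(1 - (1 - coverage) / 2)
    half_int <- z * sqrt(truth$psi11 / n_traj) / profile$kappa
    half_slo <- z * sqrt(truth$psi22 / n_traj) / profile$kappa
    ij <- bound_judgment(est$intercept, est$intercept - half_int,
                         est$intercept + half_int, coverage)
    sj <- bound_judgment(est$slope, est$slope - half_slo,
                         est$slope + half_slo, coverage)

    expert_judgment(expert_id = profile$label, group = profile$group,
                    intercept_prior = fit_skew_normal(ij, label = paste0(profile$label, ":intercept")),
                    slope_prior = fit_skew_normal(sj, label = paste0(profile$label, ":slope")),
                    trajectories = traj,
                    intercept_judgment = ij, slope_judgment = sj)
  })
}
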