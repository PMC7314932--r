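#' Record a point estimate with reasonable bounds
#'
#' Direct elicitation: after accepting a point estimate for a parameter,
#' the expert states a reasonable lower and upper bound for it. The bounds
#' are interpreted as spanning a stated central probability mass
#' (`coverage`, default 0.98, i.e. the 1st and 99th percentiles).
#'
#' @param point the accepted point estimate (score units).
#' @param lower,upper reasonable bounds, `lower < point < upper`.
#' @param coverage central probability mass the bounds span, in (0, 1).
#' @return an object of class `"bound_judgment"`.
#' @export
bound_judgment <- function(point, lower, upper, coverage = 0.98) {
  stopifnot(is.finite(point), is.finite(lower), is.finite(upper),
            is.finite(coverage))
  if (lower >= upper) stop("`lower` must be strictly below `upper`")
  if (point <= lower || point >= upper)
    stop("`point` must lie strictly inside (lower, upper)")
  if (coverage <= 0 || coverage >= 1) stop("`coverage` must be in (0, 1)")
  structure(list(point = point, lower = lower, upper = upper,
                 coverage = coverage),
            class = "bound_judgment")
}

#' @export
print.bound_judgment <- function(x, ...) {
  cat(sprintf("Bound judgment: point %.4g in (%.4g, %.4g), coverage %.3g\n",
              x$point, x$lower, x$upper, x$coverage))
  invisible(x)
}

# Relative position of the mode between the two central-coverage quantiles
# of a standard skew normal. Strictly decreasing in alpha: 0.5 at alpha = 0,
# approaching 0 (1) as alpha -> +Inf (-Inf). This monotone map is what makes
# the quantile/mode fit a one-dimensional root problem.
sn_mode_position <- function(alpha, p_lo, p_hi) {
  q <- qskewnorm(c(p_lo, p_hi), 0, 1, alpha)
  (sn_mode0(alpha) - q[1]) / (q[2] - q[1])
}

#' Fit a skew-normal prior from a point estimate with bounds
#'
#' Represents a bound judgment as a skew-normal distribution whose mode
#' equals the point estimate and whose distribution function equals
#' `(1 - coverage)/2` at the lower bound and `1 - (1 - coverage)/2` at the
#' upper bound. Symmetric bounds yield shape 0 (an ordinary normal);
#' asymmetric bounds are absorbed by the shape parameter, skewing the
#' density toward the wider side.
#'
#' With the mode pinned at the point estimate, the mode's relative position
#' between the two bound quantiles depends only on the shape parameter and
#' is strictly monotone in it, so the fit reduces to a one-dimensional root
#' problem solved to near machine precision; scale and location then follow
#' in closed form. Judgments more asymmetric than any skew normal can
#' express (point estimate too close to one bound) are rejected with the
#' attained residuals.
#'
#' @param judgment a [bound_judgment()]; alternatively pass `point`,
#'   `lower`, `upper`, `coverage` directly.
#' @param point,lower,upper,coverage used when `judgment` is missing.
#' @param label optional label attached to the returned prior.
#' @param instrument_range optional length-2 numeric; when supplied, a
#'   warning is emitted if more than 1\% of the fitted prior mass falls
#'   outside it (e.g. `c(0, 100)` for the score scale). The prior itself is
#'   never truncated.
#' @param tol maximum acceptable absolute residual on the probability scale
#'   at the two bounds; exceeding it is reported as non-convergence.
#' @return a [skew_normal_prior()].
#' @examples
#' fit_skew_normal(bound_judgment(30, 20, 40))        # symmetric: shape 0
#' fit_skew_normal(point = 30, lower = 25, upper = 45) # right-skewed
#' @export
fit_skew_normal <- function(judgment = NULL, point, lower, upper,
                            coverage = 0.98, label = NULL,
                            instrument_range = NULL, tol = 1e-4) {
  if (is.null(judgment))
    judgment <- bound_judgment(point, lower, upper, coverage)
  if (!inherits(judgment, "bound_judgment"))
    judgment <- bound_judgment(judgment$point, judgment$lower, judgment$upper,
                               if (is.null(judgment$coverage)) 0.98 else judgment$coverage)
  p_lo <- (1 - judgment$coverage) / 2
  p_hi <- 1 - p_lo
  target <- (judgment$point - judgment$lower) / (judgment$upper - judgment$lower)

  a_max <- 120
  if (abs(target - 0.5) < 1e-9) {
    a_hat <- 0
  } else {
    sgn <- if (target < 0.5) 1 else -1   # mode nearer the lower bound => right skew
    g <- function(a) sn_mode_position(a, p_lo, p_hi)
    # bracket on the half-line where the solution lives (g is decreasing)
    hi <- 4
    while (hi < a_max && sgn * (g(sgn * hi) - target) > 0) hi <- hi * 2
    if (sgn * (g(sgn * hi) - target) > 0) {
      stop(sprintf(paste0("cannot represent this judgment as a skew normal: ",
                          "the point estimate sits at relative position %.3f ",
                          "between the bounds, beyond the attainable range ",
                          "[%.3f, %.3f] at coverage %.3g"),
                   target, g(a_max), g(-a_max), judgment$coverage))
    }
    r <- stats::uniroot(function(a) g(a) - target, interval = sort(c(0, sgn * hi)),
                        tol = 1e-12)
    a_hat <- r$root
  }

  qs <- qskewnorm(c(p_lo, p_hi), 0, 1, a_hat)
  omega <- (judgment$upper - judgment$lower) / (qs[2] - qs[1])
  xi <- judgment$point - omega * sn_mode0(a_hat)

  res <- c(lower = pskewnorm(judgment$lower, xi, omega, a_hat) - p_lo,
           upper = pskewnorm(judgment$upper, xi, omega, a_hat) - p_hi)
  if (max(abs(res)) > tol)
    stop(sprintf(paste0("skew-normal fit did not converge: probability residuals ",
                        "%.2e (lower), %.2e (upper)"), res[1], res[2]))

  prior <- skew_normal_prior(xi, omega, a_hat, label = label)
  if (!is.null(instrument_range)) {
    outside <- prob(prior, instrument_range[1]) +
      (1 - prob(prior, instrument_range[2]))
    if (outside > 0.01)
      warning(sprintf("%.1f%% of the fitted prior mass lies outside [%g, %g]",
                      100 * outside, instrument_range[1], instrument_range[2]))
  }
  prior
}

#' Central credible interval of a belief distribution
#'
#' @param prior an [edist] object.
#' @param level interval probability, in (0, 1).
#' @return length-2 numeric vector `(low, high)` with
#'   `prob(prior, low) = (1 - level)/2` and `prob(prior, high) = 1 - (1 - level)/2`.
#' @export
credible_interval <- function(prior, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1)
    stop("`level` must be a single probability strictly inside (0, 1)")
  unname(quantile(prior, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

# evaluate expr under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Credible band around the implied average trajectory
#'
#' Feedback on how parameter uncertainty propagates to the average
#' trajectory. With only an intercept prior the band at every loading is
#' that prior's central credible interval (constant in the loading). With
#' both priors, the band at loading \eqn{\lambda} is the central interval
#' of \eqn{I + \lambda S} with independent draws \eqn{I} from the intercept
#' prior and \eqn{S} from the slope prior, estimated by seeded Monte Carlo.
#'
#' @param intercept_prior an [edist] for the group mean intercept.
#' @param slope_prior an [edist] for the group mean slope, or `NULL` for an
#'   intercept-only band.
#' @param loadings numeric vector of slope loadings in \[0, 1\].
#' @param level band probability, in (0, 1).
#' @param draws number of Monte Carlo draws (>= 1e5 recommended).
#' @param seed integer seed for the draws.
#' @return a data.frame with columns `loading`, `lower`, `upper`.
#' @export
band_for_trajectory <- function(intercept_prior, slope_prior = NULL,
                                loadings = c(0, 0.25, 1), level = 0.95,
                                draws = 1e5, seed = 1) {
  if (!all(is.finite(loadings)) || any(loadings < 0 | loadings > 1))
    stop("`loadings` must lie in [0, 1]")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  if (is.null(slope_prior)) {
    ci <- credible_interval(intercept_prior, level)
    return(data.frame(loading = loadings, lower = ci[1], upper = ci[2]))
  }
  sims <- with_seed(seed, {
    i_draws <- draw(intercept_prior, draws)
    s_draws <- draw(slope_prior, draws)
    list(i = i_draws, s = s_draws)
  })
  band <- t(vapply(loadings, function(lam)
    stats::quantile(sims$i + lam * sims$s, probs, names = FALSE),
    numeric(2)))
  data.frame(loading = loadings, lower = band[, 1], upper = band[, 2])
}
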