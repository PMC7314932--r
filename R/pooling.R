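#' Bundle one expert's elicited inputs and fitted priors
#'
#' Container for one expert's complete elicitation record: the raw inputs
#' (trajectories and bound judgments) and the fitted skew-normal priors for
#' the group mean intercept and slope. Group membership is plain metadata;
#' pooling never infers it.
#'
#' @param expert_id anonymized label, e.g. `"expert-03"`.
#' @param group one of `"psychologist-group"`, `"nurse-group"`, `"other"`.
#' @param intercept_prior,slope_prior fitted [skew_normal_prior()] objects.
#' @param trajectories the elicited trajectories data.frame (optional raw input).
#' @param intercept_judgment,slope_judgment the [bound_judgment()]s (optional).
#' @return an object of class `"expert_judgment"`.
#' @export
expert_judgment <- function(expert_id, group = c("other", "psychologist-group",
                                                 "nurse-group"),
                            intercept_prior, slope_prior,
                            trajectories = NULL,
                            intercept_judgment = NULL, slope_judgment = NULL) {
  group <- match.arg(group)
  if (!inherits(intercept_prior, "skew_normal_prior") ||
      !inherits(slope_prior, "skew_normal_prior"))
    stop("both `intercept_prior` and `slope_prior` must be skew_normal_prior objects")
  structure(list(expert_id = expert_id, group = group,
                 intercept_prior = intercept_prior, slope_prior = slope_prior,
                 trajectories = trajectories,
                 intercept_judgment = intercept_judgment,
                 slope_judgment = slope_judgment),
            class = "expert_judgment")
}

#' @export
print.expert_judgment <- function(x, ...) {
  cat(sprintf("Expert judgment %s (%s)\n", x$expert_id, x$group))
  cat("  intercept: "); print(x$intercept_prior)
  cat("  slope:     "); print(x$slope_prior)
  invisible(x)
}

#' Pool expert priors into a mixture (linear opinion pool)
#'
#' Aggregates K individual belief distributions into a single group prior
#' by linear (arithmetic) opinion pooling: the mixture density is
#' \eqn{\sum_k w_k f_k(x)} and the mixture CDF \eqn{\sum_k w_k F_k(x)}.
#' Weights default to equal, `1/K`, giving every expert the same say;
#' multimodality in the pooled density is retained, not smoothed away.
#'
#' @param priors a non-empty list of [edist] objects (typically
#'   [skew_normal_prior()]s for one parameter across experts).
#' @param weights optional non-negative weights, same length as `priors`;
#'   normalized to sum to 1. Default equal weights.
#' @return an object of class `c("mixture_prior", "edist")`.
#' @examples
#' m <- pool(list(dist_normal(0, 1), dist_normal(4, 1)))
#' dens(m, 2)   # 0.5*dnorm(2) + 0.5*dnorm(-2)
#' @export
pool <- function(priors, weights = NULL) {
  if (!is.list(priors) || length(priors) == 0L)
    stop("`priors` must be a non-empty list of distributions")
  if (!all(vapply(priors, inherits, logical(1), "edist")))
    stop("all elements of `priors` must be edist objects")
  k <- length(priors)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k) stop("`weights` must match the number of priors")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("`weights` must be finite and non-negative")
  s <- sum(weights)
  if (s <= 0) stop("`weights` must not all be zero")
  structure(list(components = priors, weights = weights / s),
            class = c("mixture_prior", "edist"))
}

#' @export
dens.mixture_prior <- function(d, x, ...) {
  out <- numeric(length(x))
  for (k in seq_along(d$components))
    out <- out + d$weights[k] * dens(d$components[[k]], x)
  out
}

#' @export
ldens.mixture_prior <- function(d, x, ...) {
  # log-sum-exp over components so far-tail evaluations do not underflow
  lmat <- matrix(0, length(x), length(d$components))
  for (k in seq_along(d$components))
    lmat[, k] <- log(d$weights[k]) + ldens(d$components[[k]], x)
  mx <- apply(lmat, 1, max)
  out <- mx + log(rowSums(exp(lmat - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

#' @export
prob.mixture_prior <- function(d, x, ...) {
  out <- numeric(length(x))
  for (k in seq_along(d$components))
    out <- out + d$weights[k] * prob(d$components[[k]], x)
  out
}

#' @export
quantile.mixture_prior <- function(x, probs = c(0.025, 0.975), ...) {
  # bracket from component quantiles, then invert the mixture CDF
  vapply(probs, function(p) {
    qs <- vapply(x$components, function(cmp) quantile(cmp, p), numeric(1))
    lo <- min(qs) - 1e-9
    hi <- max(qs) + 1e-9
    if (prob(x, lo) >= p) return(lo)
    stats::uniroot(function(z) prob(x, z) - p, c(lo, hi), tol = 1e-11)$root
  }, numeric(1))
}

#' @export
draw.mixture_prior <- function(d, n, ...) {
  idx <- sample.int(length(d$components), n, replace = TRUE, prob = d$weights)
  out <- numeric(n)
  for (k in unique(idx)) {
    sel <- idx == k
    out[sel] <- draw(d$components[[k]], sum(sel))
  }
  out
}

#' @export
dist_mean.mixture_prior <- function(d, ...) {
  sum(d$weights * vapply(d$components, dist_mean, numeric(1)))
}

#' @export
dist_var.mixture_prior <- function(d, ...) {
  mu <- vapply(d$components, dist_mean, numeric(1))
  v <- vapply(d$components, dist_var, numeric(1))
  m <- sum(d$weights * mu)
  sum(d$weights * (v + mu^2)) - m^2
}

#' @export
dist_support.mixture_prior <- function(d, ...) {
  sup <- vapply(d$components, dist_support, numeric(2))
  c(min(sup[1, ]), max(sup[2, ]))
}

#' @export
print.mixture_prior <- function(x, ...) {
  cat(sprintf("Mixture prior with %d components (linear opinion pool)\n",
              length(x$components)))
  for (k in seq_along(x$components)) {
    cat(sprintf("  w = %.4g: ", x$weights[k]))
    print(x$components[[k]])
  }
  invisible(x)
}

#' Pool one parameter across a list of expert judgments
#'
#' Convenience wrapper around [pool()]: selects the intercept or slope
#' prior from each [expert_judgment()], optionally restricted to one group,
#' and pools them with equal weights.
#'
#' @param judgments list of [expert_judgment()] objects.
#' @param parameter `"intercept"` or `"slope"`.
#' @param group optional group filter (`"psychologist-group"`,
#'   `"nurse-group"`); default pools all judgments.
#' @return a `mixture_prior`.
#' @export
pool_judgments <- function(judgments, parameter = c("intercept", "slope"),
                           group = NULL) {
  parameter <- match.arg(parameter)
  if (!is.null(group)) {
    judgments <- Filter(function(j) identical(j$group, group), judgments)
    if (length(judgments) == 0L)
      stop(sprintf("no judgments in group '%s'", group))
  }
  field <- paste0(parameter, "_prior")
  pool(lapply(judgments, `[[`, field))
}
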