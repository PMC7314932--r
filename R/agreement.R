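#' Kullback--Leibler divergence between belief distributions
#'
#' Computes \eqn{KL(p \| q) = \int p(x)\log\{p(x)/q(x)\}\,dx} in nats: the
#' information lost when distribution `p` is approximated by distribution
#' `q`. For prior--data (dis)agreement, `p` is the (normal approximation of
#' the) reference posterior and `q` a candidate prior, so a larger value
#' means the prior is a worse stand-in for what the data say.
#'
#' Closed forms are used when both distributions are normal or when `q` is
#' uniform and `p` normal; every other pair is handled by adaptive
#' quadrature over the effective support of `p` (its own support
#' intersected with mean +/- 12 SD). If `q` assigns zero density to a
#' region holding more than `1e-12` of `p`'s mass, the divergence is
#' `+Inf`.
#'
#' @param p,q [edist] objects (`p` the reference, `q` the approximation).
#' @param method `"auto"` (closed form when available), `"closed"` (error
#'   if no closed form exists) or `"quadrature"`.
#' @return a non-negative number of nats, possibly `+Inf`.
#' @examples
#' kl_divergence(dist_normal(0, 1), dist_normal(1, 1))   # 0.5 exactly
#' kl_divergence(dist_normal(22.7, sqrt(1.3)), dist_uniform(0, 100))
#' @export
kl_divergence <- function(p, q, method = c("auto", "closed", "quadrature")) {
  method <- match.arg(method)
  if (!inherits(p, "edist") || !inherits(q, "edist"))
    stop("`p` and `q` must be edist objects")

  if (method != "quadrature") {
    cf <- kl_closed_form(p, q)
    if (!is.null(cf)) return(max(cf, 0))
    if (method == "closed")
      stop("no closed form for this pair of distributions")
  }
  kl_quadrature(p, q)
}

# closed forms; NULL when none applies
kl_closed_form <- function(p, q) {
  if (inherits(p, "normal_dist") && inherits(q, "normal_dist")) {
    return(log(q$sd / p$sd) + (p$sd^2 + (p$mean - q$mean)^2) / (2 * q$sd^2) - 0.5)
  }
  if (inherits(q, "uniform_dist")) {
    mass_out <- prob(p, q$min) + (1 - prob(p, q$max))
    if (mass_out > 1e-12) return(Inf)
    if (inherits(p, "normal_dist"))
      return(log(q$max - q$min) - 0.5 * log(2 * pi * exp(1) * p$sd^2))
    if (inherits(p, "uniform_dist"))
      return(log(q$max - q$min) - log(p$max - p$min))
  }
  NULL
}

# effective integration range of p: own support clipped to mean +/- 12 SD
effective_support <- function(p) {
  sup <- dist_support(p)
  m <- dist_mean(p)
  s <- sqrt(dist_var(p))
  c(max(sup[1], m - 12 * s), min(sup[2], m + 12 * s))
}

kl_quadrature <- function(p, q) {
  qsup <- dist_support(q)
  mass_out <- prob(p, qsup[1]) + (1 - prob(p, qsup[2]))
  if (mass_out > 1e-12) return(Inf)
  rng <- effective_support(p)
  rng <- c(max(rng[1], qsup[1]), min(rng[2], qsup[2]))
  # work on the log scale: far-tail densities underflow to zero long before
  # their logs do, and the integrand p*(log p - log q) vanishes with p
  integrand <- function(x) {
    lp <- ldens(p, x)
    lq <- ldens(q, x)
    out <- numeric(length(x))
    pos <- is.finite(lp)
    out[pos] <- exp(lp[pos]) * (lp[pos] - lq[pos])
    out
  }
  val <- tryCatch(
    stats::integrate(integrand, rng[1], rng[2], subdivisions = 2000L,
                     rel.tol = 1e-10, abs.tol = 1e-10)$value,
    error = function(e)
      stop(sprintf("KL quadrature failed over [%.4g, %.4g]: %s",
                   rng[1], rng[2], conditionMessage(e))))
  if (val < 0 && val > -1e-8) val <- 0
  val
}

#' Tabulate prior-data (dis)agreement for a set of candidate priors
#'
#' Builds the ranking table of Kullback--Leibler divergences from the
#' reference posterior marginals (group mean intercept and slope) to each
#' candidate prior: individual experts, pooled groups and benchmarks. By
#' default the posterior enters through its moment-matched normal
#' approximation.
#'
#' @param posterior either an `"lgm_posterior"` from [fit_lgm()] (its
#'   `alpha1`/`alpha2` marginals are moment-matched to normals) or a list
#'   `list(intercept = <edist>, slope = <edist>)` of posterior
#'   approximations.
#' @param priors a named list; each element is an [expert_judgment()] or a
#'   list `list(intercept = <edist>, slope = <edist>)`. Names become the
#'   row labels, in input order.
#' @return an object of class `c("agreement_table", "data.frame")` with
#'   columns `label`, `kl_intercept`, `kl_slope` (nats, full precision).
#' @examples
#' post <- list(intercept = dist_normal(22.7, sqrt(1.3)),
#'              slope = dist_normal(-14.6, sqrt(1.9)))
#' bm <- list(
#'   "Benchmark 1" = list(intercept = dist_uniform(0, 100),
#'                        slope = dist_uniform(-100, 100)),
#'   "Benchmark 2" = list(intercept = dist_normal(0, 1e4),
#'                        slope = dist_normal(0, 1e4)))
#' build_agreement_table(post, bm)
#' @export
build_agreement_table <- function(posterior, priors) {
  ref <- posterior_pair(posterior)
  if (length(priors) && is.null(names(priors)))
    names(priors) <- paste("prior", seq_along(priors))
  rows <- lapply(names(priors), function(lbl) {
    pr <- prior_pair(priors[[lbl]], lbl)
    data.frame(label = lbl,
               kl_intercept = kl_divergence(ref$intercept, pr$intercept),
               kl_slope = kl_divergence(ref$slope, pr$slope))
  })
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(label = character(), kl_intercept = numeric(),
                  kl_slope = numeric())
  stopifnot(all(tab$kl_intercept >= 0), all(tab$kl_slope >= 0))
  structure(tab,
            reference = describe_reference(ref),
            class = c("agreement_table", "data.frame"))
}

posterior_pair <- function(posterior) {
  if (inherits(posterior, "lgm_posterior"))
    return(list(intercept = posterior_marginal(posterior, "alpha1"),
                slope = posterior_marginal(posterior, "alpha2")))
  if (is.list(posterior) && inherits(posterior$intercept, "edist") &&
      inherits(posterior$slope, "edist"))
    return(posterior[c("intercept", "slope")])
  stop("`posterior` must be an lgm_posterior or a list with edist elements `intercept` and `slope`")
}

prior_pair <- function(x, label) {
  if (inherits(x, "expert_judgment"))
    return(list(intercept = x$intercept_prior, slope = x$slope_prior))
  if (is.list(x) && inherits(x$intercept, "edist") && inherits(x$slope, "edist"))
    return(x[c("intercept", "slope")])
  stop(sprintf("prior '%s' must be an expert_judgment or a list with edist elements `intercept` and `slope`",
               label))
}

describe_reference <- function(ref) {
  fmt <- function(d) {
    if (inherits(d, "normal_dist"))
      sprintf("N(%.4g, var %.4g)", d$mean, d$sd^2)
    else class(d)[1]
  }
  sprintf("reference posterior: intercept %s, slope %s",
          fmt(ref$intercept), fmt(ref$slope))
}

#' @export
print.agreement_table <- function(x, ...) {
  cat("Prior-data (dis)agreement, KL(posterior || prior) in nats\n")
  if (!is.null(attr(x, "reference"))) cat(" ", attr(x, "reference"), "\n")
  df <- data.frame(label = x$label,
                   kl_intercept = sprintf("%.2f", x$kl_intercept),
                   kl_slope = sprintf("%.2f", x$kl_slope))
  print(df, row.names = FALSE)
  invisible(x)
}
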