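#' One-dimensional belief distributions
#'
#' A small S3 hierarchy of one-dimensional distributions used throughout the
#' elicitation pipeline: normal, uniform, skew-normal priors and mixture
#' (pooled) priors all inherit from class `"edist"` and expose a density
#' [dens()], a distribution function [prob()], a [quantile()] method and
#' random draws via [draw()].
#'
#' @param mean,sd mean and standard deviation of a normal distribution.
#' @param min,max support endpoints of a uniform distribution.
#' @return an object of class `"edist"`.
#' @examples
#' p <- dist_normal(22.7, sqrt(1.3))
#' dens(p, 22.7)
#' prob(p, 22.7)
#' quantile(p, c(0.025, 0.975))
#' @name edist
NULL

#' @rdname edist
#' @export
dist_normal <- function(mean = 0, sd = 1) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0)
  structure(list(mean = mean, sd = sd),
            class = c("normal_dist", "edist"))
}

#' @rdname edist
#' @export
dist_uniform <- function(min = 0, max = 1) {
  stopifnot(is.finite(min), is.finite(max), min < max)
  structure(list(min = min, max = max),
            class = c("uniform_dist", "edist"))
}

#' Evaluate the density of a belief distribution
#' @param d an [edist] object.
#' @param x numeric vector of evaluation points.
#' @param ... unused.
#' @export
dens <- function(d, x, ...) UseMethod("dens")

#' Evaluate the cumulative distribution function of a belief distribution
#' @inheritParams dens
#' @export
prob <- function(d, x, ...) UseMethod("prob")

#' Draw random samples from a belief distribution
#' @param d an [edist] object.
#' @param n number of draws.
#' @param ... unused.
#' @export
draw <- function(d, n, ...) UseMethod("draw")

# log density; internal, used by the KL quadrature to avoid tail underflow
ldens <- function(d, x, ...) UseMethod("ldens")
#' @export
ldens.normal_dist <- function(d, x, ...) stats::dnorm(x, d$mean, d$sd, log = TRUE)
#' @export
ldens.uniform_dist <- function(d, x, ...) stats::dunif(x, d$min, d$max, log = TRUE)
#' @export
ldens.skew_normal_prior <- function(d, x, ...)
  dskewnorm(x, d$xi, d$omega, d$alpha, log = TRUE)
#' @export
ldens.edist <- function(d, x, ...) log(dens(d, x))

#' Mean, variance and support of a belief distribution
#' @inheritParams dens
#' @return `dist_mean` and `dist_var` return a single numeric; `dist_support`
#'   a length-2 numeric vector (possibly infinite) outside which the density
#'   is exactly zero.
#' @export
dist_mean <- function(d, ...) UseMethod("dist_mean")

#' @rdname dist_mean
#' @export
dist_var <- function(d, ...) UseMethod("dist_var")

#' @rdname dist_mean
#' @export
dist_support <- function(d, ...) UseMethod("dist_support")

## normal ---------------------------------------------------------------

#' @export
dens.normal_dist <- function(d, x, ...) stats::dnorm(x, d$mean, d$sd)
#' @export
prob.normal_dist <- function(d, x, ...) stats::pnorm(x, d$mean, d$sd)
#' @export
quantile.normal_dist <- function(x, probs = c(0.025, 0.975), ...)
  stats::qnorm(probs, x$mean, x$sd)
#' @export
draw.normal_dist <- function(d, n, ...) stats::rnorm(n, d$mean, d$sd)
#' @export
dist_mean.normal_dist <- function(d, ...) d$mean
#' @export
dist_var.normal_dist <- function(d, ...) d$sd^2
#' @export
dist_support.normal_dist <- function(d, ...) c(-Inf, Inf)
#' @export
print.normal_dist <- function(x, ...) {
  cat(sprintf("Normal(mean = %g, sd = %g)\n", x$mean, x$sd))
  invisible(x)
}

## uniform --------------------------------------------------------------

#' @export
dens.uniform_dist <- function(d, x, ...) stats::dunif(x, d$min, d$max)
#' @export
prob.uniform_dist <- function(d, x, ...) stats::punif(x, d$min, d$max)
#' @export
quantile.uniform_dist <- function(x, probs = c(0.025, 0.975), ...)
  stats::qunif(probs, x$min, x$max)
#' @export
draw.uniform_dist <- function(d, n, ...) stats::runif(n, d$min, d$max)
#' @export
dist_mean.uniform_dist <- function(d, ...) (d$min + d$max) / 2
#' @export
dist_var.uniform_dist <- function(d, ...) (d$max - d$min)^2 / 12
#' @export
dist_support.uniform_dist <- function(d, ...) c(d$min, d$max)
#' @export
print.uniform_dist <- function(x, ...) {
  cat(sprintf("Uniform(%g, %g)\n", x$min, x$max))
  invisible(x)
}

## skew-normal prior ----------------------------------------------------

#' Construct a skew-normal prior
#'
#' The parametric form used to represent a single elicited belief about a
#' growth-model parameter: a skew-normal distribution in the direct
#' (location, scale, shape) parameterization. Shape 0 is the symmetric
#' normal. See [fit_skew_normal()] for fitting one from a point estimate
#' with bounds.
#'
#' @param xi location (score units).
#' @param omega scale, > 0 (score units).
#' @param alpha shape (unitless); 0 gives a normal distribution.
#' @param label optional free-text label (e.g. parameter or expert id).
#' @return an object of class `c("skew_normal_prior", "edist")`.
#' @export
skew_normal_prior <- function(xi, omega, alpha = 0, label = NULL) {
  stopifnot(is.finite(xi), is.finite(omega), is.finite(alpha))
  if (omega <= 0) stop("scale `omega` must be > 0")
  structure(list(xi = xi, omega = omega, alpha = alpha, label = label),
            class = c("skew_normal_prior", "edist"))
}

#' @export
dens.skew_normal_prior <- function(d, x, ...) dskewnorm(x, d$xi, d$omega, d$alpha)
#' @export
prob.skew_normal_prior <- function(d, x, ...) pskewnorm(x, d$xi, d$omega, d$alpha)
#' @export
quantile.skew_normal_prior <- function(x, probs = c(0.025, 0.975), ...)
  qskewnorm(probs, x$xi, x$omega, x$alpha)
#' @export
draw.skew_normal_prior <- function(d, n, ...) rskewnorm(n, d$xi, d$omega, d$alpha)
#' @export
dist_mean.skew_normal_prior <- function(d, ...) skewnorm_mean(d$xi, d$omega, d$alpha)
#' @export
dist_var.skew_normal_prior <- function(d, ...) skewnorm_var(d$xi, d$omega, d$alpha)
#' @export
dist_support.skew_normal_prior <- function(d, ...) c(-Inf, Inf)
#' @export
print.skew_normal_prior <- function(x, ...) {
  cat(sprintf("Skew-normal prior%s: xi = %.4g, omega = %.4g, alpha = %.4g\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$xi, x$omega, x$alpha))
  invisible(x)
}
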