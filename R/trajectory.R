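#' Validate a set of fictive individual trajectories
#'
#' A trajectory is one fictive individual's linear symptom path on the
#' standardized 0--100 score scale, summarized by its score at the first
#' time point (`start`, the intercept scale) and at 12 months (`end`, one
#' slope-unit later). Elicitation asks an expert for a small set of such
#' representative individuals (ten by default) rather than for the model
#' parameters directly.
#'
#' @param trajectories a data.frame with numeric columns `start` and `end`
#'   (optionally `subject_label`).
#' @return the validated data.frame, invisibly for `validate_trajectories`.
#' @export
validate_trajectories <- function(trajectories) {
  if (!is.data.frame(trajectories))
    stop("`trajectories` must be a data.frame with columns `start` and `end`")
  if (!all(c("start", "end") %in% names(trajectories)))
    stop("`trajectories` must have columns `start` and `end`")
  if (nrow(trajectories) == 0L) stop("no trajectories")
  for (col in c("start", "end")) {
    v <- trajectories[[col]]
    if (!is.numeric(v) || anyNA(v))
      stop(sprintf("column `%s` must be numeric with no missing values", col))
    bad <- which(v < 0 | v > 100)
    if (length(bad))
      stop(sprintf("trajectory %s: `%s` value %g outside the score scale [0, 100]",
                   bad[1], col, v[bad[1]]))
  }
  invisible(trajectories)
}

#' Reduce individual trajectories to group-mean point estimates
#'
#' Indirect elicitation: the expert supplies fictive individual
#' trajectories, and the point estimate for the group mean intercept is the
#' arithmetic mean of the start values while the point estimate for the
#' group mean slope (change per year) is the arithmetic mean of the
#' individual changes `end - start`.
#'
#' @inheritParams validate_trajectories
#' @return an object of class `"point_estimates"`: a list with elements
#'   `intercept` and `slope` (score units, and score units per year).
#' @examples
#' tr <- data.frame(start = c(10, 20, 30), end = c(10, 30, 20))
#' derive_point_estimates(tr)
#' @export
derive_point_estimates <- function(trajectories) {
  validate_trajectories(trajectories)
  if (nrow(trajectories) < 3L)
    warning("fewer than 3 trajectories: the average is weakly supported")
  est <- list(intercept = mean(trajectories$start),
              slope = mean(trajectories$end - trajectories$start))
  class(est) <- "point_estimates"
  est
}

#' @export
print.point_estimates <- function(x, ...) {
  cat(sprintf("Point estimates: intercept = %.4g, slope = %.4g (per year)\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Evaluate the implied average trajectory
#'
#' Feedback for the second elicitation step: the average trajectory implied
#' by the point estimates, evaluated at the requested slope loadings. Under
#' the linear growth model the score at loading \eqn{\lambda} is
#' `intercept + lambda * slope`, with loading 0 the first time point and
#' loading 1 the 12-month measurement.
#'
#' @param estimates a `"point_estimates"` object (or list with `intercept`
#'   and `slope`).
#' @param loadings sorted numeric vector of slope loadings in \[0, 1\].
#' @return a data.frame with columns `loading` and `score`.
#' @examples
#' average_trajectory(list(intercept = 30, slope = -10), c(0, 0.25, 1))
#' @export
average_trajectory <- function(estimates, loadings = c(0, 0.25, 1)) {
  if (!all(is.finite(loadings)) || any(loadings < 0 | loadings > 1))
    stop("`loadings` must lie in [0, 1]")
  if (is.unsorted(loadings)) stop("`loadings` must be sorted increasingly")
  data.frame(loading = loadings,
             score = estimates$intercept + loadings * estimates$slope)
}
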