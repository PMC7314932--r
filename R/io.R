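#' Read and write elicited judgment files
#'
#' Expert judgments are exchanged as JSON: one record per expert holding
#' the anonymized id, group label, raw trajectories, the bound judgments
#' for intercept and slope, and (optionally) the fitted skew-normal
#' priors. On reading, every invariant of the contained types is enforced
#' with errors naming the offending expert and field; records without
#' stored priors get them refitted from the bound judgments, so a file of
#' raw inputs alone is a valid starting point.
#'
#' @param path file path of the JSON judgment file.
#' @param judgments a list of [expert_judgment()] objects.
#' @return `read_judgments` returns a list of [expert_judgment()]s;
#'   `write_judgments` is called for its side effect and returns `path`
#'   invisibly.
#' @name judgment_io
NULL

prior_to_list <- function(p) {
  list(label = p$label, family = "skew-normal",
       xi = p$xi, omega = p$omega, alpha = p$alpha)
}

prior_from_list <- function(x, where) {
  for (f in c("xi", "omega", "alpha"))
    if (is.null(x[[f]]) || !is.numeric(x[[f]]))
      stop(sprintf("%s: prior field `%s` missing or non-numeric", where, f))
  if (!is.null(x$family) && !identical(x$family, "skew-normal"))
    stop(sprintf("%s: unsupported prior family '%s'", where, x$family))
  skew_normal_prior(x$xi, x$omega, x$alpha,
                    label = if (is.null(x$label)) NULL else x$label)
}

judgment_from_list <- function(x, where) {
  for (f in c("point", "lower", "upper"))
    if (is.null(x[[f]]) || !is.numeric(x[[f]]))
      stop(sprintf("%s: bound field `%s` missing or non-numeric", where, f))
  cov <- if (is.null(x$coverage)) 0.98 else x$coverage
  tryCatch(bound_judgment(x$point, x$lower, x$upper, cov),
           error = function(e) stop(sprintf("%s: %s", where, conditionMessage(e))))
}

#' @rdname judgment_io
#' @export
write_judgments <- function(judgments, path) {
  recs <- lapply(judgments, function(j) {
    stopifnot(inherits(j, "expert_judgment"))
    rec <- list(expert_id = j$expert_id, group = j$group)
    if (!is.null(j$trajectories))
      rec$trajectories <- lapply(seq_len(nrow(j$trajectories)), function(i)
        list(subject_label = as.character(j$trajectories$subject_label[i]),
             start = j$trajectories$start[i], end = j$trajectories$end[i]))
    if (!is.null(j$intercept_judgment))
      rec$intercept <- unclass(j$intercept_judgment)
    if (!is.null(j$slope_judgment))
      rec$slope <- unclass(j$slope_judgment)
    rec$intercept_prior <- prior_to_list(j$intercept_prior)
    rec$slope_prior <- prior_to_list(j$slope_prior)
    rec
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname judgment_io
#' @export
read_judgments <- function(path) {
  if (!file.exists(path)) stop(sprintf("judgment file not found: %s", path))
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(recs)) stop("judgment file must hold an array of expert records")
  lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    id <- if (is.null(r$expert_id)) sprintf("record %d", i) else r$expert_id
    where <- sprintf("expert '%s'", id)
    if (is.null(r$expert_id)) stop(sprintf("%s: field `expert_id` missing", where))
    group <- if (is.null(r$group)) "other" else r$group
    if (!group %in% c("psychologist-group", "nurse-group", "other"))
      stop(sprintf("%s: unknown group '%s'", where, group))

    traj <- NULL
    if (!is.null(r$trajectories)) {
      traj <- do.call(rbind, lapply(seq_along(r$trajectories), function(k) {
        tr <- r$trajectories[[k]]
        for (f in c("start", "end"))
          if (is.null(tr[[f]]) || !is.numeric(tr[[f]]))
            stop(sprintf("%s: trajectory %d field `%s` missing or non-numeric",
                         where, k, f))
        data.frame(subject_label = if (is.null(tr$subject_label))
          sprintf("fictive-%d", k) else tr$subject_label,
          start = tr$start, end = tr$end)
      }))
      tryCatch(validate_trajectories(traj),
               error = function(e) stop(sprintf("%s: %s", where,
                                                conditionMessage(e))))
    }

    ij <- if (!is.null(r$intercept))
      judgment_from_list(r$intercept, paste0(where, ", intercept"))
    sj <- if (!is.null(r$slope))
      judgment_from_list(r$slope, paste0(where, ", slope"))

    ip <- if (!is.null(r$intercept_prior))
      prior_from_list(r$intercept_prior, paste0(where, ", intercept_prior"))
    else if (!is.null(ij)) fit_skew_normal(ij)
    else stop(sprintf("%s: neither `intercept_prior` nor `intercept` bounds present", where))
    sp <- if (!is.null(r$slope_prior))
      prior_from_list(r$slope_prior, paste0(where, ", slope_prior"))
    else if (!is.null(sj)) fit_skew_normal(sj)
    else stop(sprintf("%s: neither `slope_prior` nor `slope` bounds present", where))

    expert_judgment(r$expert_id, group, ip, sp, trajectories = traj,
                    intercept_judgment = ij, slope_judgment = sj)
  })
}

#' Read raw trajectories from CSV
#'
#' CSV alternative for the indirect-elicitation inputs: columns
#' `expert_id`, `subject_label`, `start`, `end`, one row per fictive
#' individual. Returns one validated trajectory data.frame per expert,
#' ready for [derive_point_estimates()].
#'
#' @param path CSV file path with a header row.
#' @return a named list (by `expert_id`) of trajectory data.frames.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop(sprintf("trajectory file not found: %s", path))
  df <- utils::read.csv(path)
  need <- c("expert_id", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("trajectory CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (!"subject_label" %in% names(df))
    df$subject_label <- stats::ave(seq_len(nrow(df)), df$expert_id,
                                   FUN = seq_along)
  out <- split(df[, c("subject_label", "start", "end")], df$expert_id)
  for (id in names(out)) {
    rownames(out[[id]]) <- NULL
    tryCatch(validate_trajectories(out[[id]]),
             error = function(e) stop(sprintf("expert '%s': %s", id,
                                              conditionMessage(e))))
  }
  out
}

#' Read and write single fitted priors and mixtures
#'
#' Fitted priors serialize as
#' `{label, family: "skew-normal", xi, omega, alpha}`; mixtures as
#' `{components: [...], weights: [...]}`. Numeric round trips are lossless
#' to full double precision.
#'
#' @param prior a [skew_normal_prior()].
#' @param mixture a `mixture_prior` from [pool()].
#' @param path JSON file path.
#' @name prior_io
NULL

#' @rdname prior_io
#' @export
write_prior <- function(prior, path) {
  stopifnot(inherits(prior, "skew_normal_prior"))
  jsonlite::write_json(prior_to_list(prior), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname prior_io
#' @export
read_prior <- function(path) {
  prior_from_list(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  sprintf("file '%s'", path))
}

#' @rdname prior_io
#' @export
write_mixture <- function(mixture, path) {
  stopifnot(inherits(mixture, "mixture_prior"))
  jsonlite::write_json(
    list(components = lapply(mixture$components, prior_to_list),
         weights = mixture$weights),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname prior_io
#' @export
read_mixture <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  comps <- lapply(seq_along(x$components), function(k)
    prior_from_list(x$components[[k]], sprintf("component %d", k)))
  pool(comps, weights = as.numeric(unlist(x$weights)))
}

#' Read and write longitudinal score tables
#'
#' Scores travel as CSV with a header row: column `id` plus one column per
#' wave (`t1`, `t2`, `t3`, ...), values on the standardized 0--100 scale.
#'
#' @param path CSV file path.
#' @param scores a data.frame as produced by [simulate_scores()].
#' @name score_io
NULL

#' @rdname score_io
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' @rdname score_io
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop(sprintf("score file not found: %s", path))
  df <- utils::read.csv(path)
  if (!"id" %in% names(df))
    stop("score CSV must have a header with an `id` column")
  wave_cols <- setdiff(names(df), "id")
  if (length(wave_cols) < 2) stop("score CSV must have at least two wave columns")
  for (col in wave_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) stop(sprintf("score column `%s` is not numeric", col))
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad))
      stop(sprintf("row %d: `%s` = %g outside the score scale [0, 100]",
                   bad[1], col, v[bad[1]]))
  }
  df
}

#' Write a prior-data agreement table
#'
#' The CSV mirrors the published presentation: columns `label`,
#' `kl_intercept`, `kl_slope`, values displayed at 2 decimals. A companion
#' JSON file (same path with extension `.json`) keeps full precision.
#'
#' @param table an `agreement_table` from [build_agreement_table()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_agreement_table <- function(table, path) {
  stopifnot(inherits(table, "agreement_table"))
  disp <- data.frame(label = table$label,
                     kl_intercept = sprintf("%.2f", table$kl_intercept),
                     kl_slope = sprintf("%.2f", table$kl_slope))
  utils::write.csv(disp, path, row.names = FALSE, quote = 1)
  json_path <- sub("\\.csv$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  jsonlite::write_json(
    list(reference = attr(table, "reference"),
         rows = lapply(seq_len(nrow(table)), function(i)
           list(label = table$label[i],
                kl_intercept = table$kl_intercept[i],
                kl_slope = table$kl_slope[i]))),
    json_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write and read posterior summaries
#'
#' A fitted posterior serializes as JSON holding the per-parameter
#' marginal mean and variance of the moment-matched normal approximation,
#' plus convergence diagnostics and the MCMC settings. Draws are not
#' serialized; refit with the stored seed to regenerate them.
#'
#' @param posterior an `"lgm_posterior"` from [fit_lgm()].
#' @param path JSON file path.
#' @return `read_posterior` returns a list with elements `intercept` and
#'   `slope` ([dist_normal()] approximations, directly usable with
#'   [build_agreement_table()]), `summary` (data.frame) and `converged`.
#' @name posterior_io
NULL

#' @rdname posterior_io
#' @export
write_posterior <- function(posterior, path) {
  stopifnot(inherits(posterior, "lgm_posterior"))
  s <- posterior$summary
  params <- stats::setNames(lapply(seq_len(nrow(s)), function(i)
    list(mean = s$mean[i], var = s$var[i], rhat = s$rhat[i], ess = s$ess[i])),
    s$parameter)
  jsonlite::write_json(list(params = params, converged = posterior$converged,
                            n = posterior$n, mcmc = posterior$mcmc),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname posterior_io
#' @export
read_posterior <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  s <- do.call(rbind, lapply(names(x$params), function(p)
    data.frame(parameter = p, mean = x$params[[p]]$mean,
               var = x$params[[p]]$var,
               rhat = if (is.null(x$params[[p]]$rhat)) NA_real_ else x$params[[p]]$rhat,
               ess = if (is.null(x$params[[p]]$ess)) NA_real_ else x$params[[p]]$ess)))
  list(intercept = dist_normal(x$params$alpha1$mean, sqrt(x$params$alpha1$var)),
       slope = dist_normal(x$params$alpha2$mean, sqrt(x$params$alpha2$var)),
       summary = s, converged = isTRUE(x$converged))
}
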