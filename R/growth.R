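#' Indices of the exponential window of a growth curve
#'
#' The exponential part of an OD600 curve is defined relative to the maximum
#' observed density (the stationary plateau): readings between 0.05 and 0.75
#' times the maximum, bounds inclusive, are in the window.
#'
#' @param g A [growth_curve()].
#' @param lower,upper Window bounds as fractions of the maximum OD600.
#' @return Integer indices into `g$time_min` / `g$od600`.
#' @export
exponential_window <- function(g, lower = 0.05, upper = 0.75) {
  stopifnot(inherits(g, "growth_curve"))
  mx <- max(g$od600)
  idx <- which(g$od600 >= lower * mx & g$od600 <= upper * mx)
  if (length(idx) < 3L) {
    stopf(
      "only %d reading(s) fall in the exponential window [%g, %g] x max OD; need >= 3",
      length(idx), lower, upper
    )
  }
  idx
}

#' Fit the doubling time of one growth curve
#'
#' Ordinary least squares of log_e(OD600) on time (minutes) over the
#' exponential window; the doubling time is ln(2) divided by the fitted
#' slope. A non-positive slope (no growth within the window) is an error.
#'
#' @param g A [growth_curve()].
#' @param lower,upper Window bounds, see [exponential_window()].
#' @return A list with `slope` (per-minute log_e growth rate),
#'   `doubling_time_min`, `n_points_used`, and the window indices.
#' @export
fit_doubling_time <- function(g, lower = 0.05, upper = 0.75) {
  idx <- exponential_window(g, lower, upper)
  t <- g$time_min[idx]
  y <- log(g$od600[idx])
  fit <- stats::lm.fit(cbind(1, t), y)
  slope <- unname(fit$coefficients[2L])
  if (!is.finite(slope) || slope <= 0) {
    stopf(
      "non-positive growth slope (%g/min) in exponential window of replicate '%s'",
      slope, g$replicate_id
    )
  }
  list(
    replicate_id = g$replicate_id,
    condition_id = g$condition_id,
    slope = slope,
    doubling_time_min = log(2) / slope,
    n_points_used = length(idx),
    window = idx
  )
}

#' Combine per-replicate doubling times into a condition estimate
#'
#' Mean and two-sided 95% confidence interval from the t-distribution with
#' n-1 degrees of freedom over the replicate doubling times. A single
#' replicate yields a flagged point estimate with an undefined interval.
#'
#' @param fits List of per-replicate fits from [fit_doubling_time()], or a
#'   numeric vector of doubling times.
#' @param condition_id Condition label for the estimate.
#' @param conf_level Confidence level, default 0.95.
#' @return A `doubling_time_estimate` list.
#' @export
summarize_replicates <- function(fits, condition_id = NULL, conf_level = 0.95) {
  if (is.numeric(fits)) {
    dt <- fits
    slopes <- log(2) / dt
    n_pts <- rep(NA_integer_, length(dt))
    reps <- as.character(seq_along(dt))
  } else {
    dt <- vapply(fits, `[[`, numeric(1), "doubling_time_min")
    slopes <- vapply(fits, `[[`, numeric(1), "slope")
    n_pts <- vapply(fits, `[[`, integer(1), "n_points_used")
    reps <- vapply(fits, `[[`, character(1), "replicate_id")
    if (is.null(condition_id)) condition_id <- fits[[1L]]$condition_id
  }
  n <- length(dt)
  if (n < 1L) stopf("no replicate estimates supplied")
  m <- mean(dt)
  if (n == 1L) {
    ci <- c(NA_real_, NA_real_)
    flagged <- TRUE
    note <- "single replicate: confidence interval undefined"
  } else {
    se <- stats::sd(dt) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1L)
    ci <- m + c(-1, 1) * tq * se
    flagged <- FALSE
    note <- ""
  }
  structure(
    list(
      condition_id = if (is.null(condition_id)) NA_character_ else condition_id,
      replicate_ids = reps,
      per_replicate = dt,
      slope = slopes,
      n_points_used = n_pts,
      mean = m,
      ci95_low = ci[1L],
      ci95_high = ci[2L],
      conf_level = conf_level,
      flagged = flagged,
      note = note
    ),
    class = "doubling_time_estimate"
  )
}

#' Doubling-time estimates for every condition in a curve set
#'
#' @param curves List of [growth_curve()] objects (e.g. from
#'   [read_growth_curves()]).
#' @param lower,upper Window bounds passed to [fit_doubling_time()].
#' @return A `doubling_time_set`: named list of `doubling_time_estimate`
#'   objects, one per condition_id.
#' @export
estimate_doubling_times <- function(curves, lower = 0.05, upper = 0.75) {
  cond <- vapply(curves, `[[`, character(1), "condition_id")
  out <- lapply(split(curves, cond), function(cs) {
    summarize_replicates(lapply(cs, fit_doubling_time, lower = lower, upper = upper))
  })
  class(out) <- "doubling_time_set"
  out
}

#' @export
print.doubling_time_estimate <- function(x, ...) {
  cat(sprintf(
    "<doubling_time_estimate> %s: mean %.1f min (95%% CI %.1f-%.1f), %d replicate(s)%s\n",
    x$condition_id, x$mean, x$ci95_low, x$ci95_high, length(x$per_replicate),
    if (x$flagged) " [flagged]" else ""
  ))
  invisible(x)
}
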