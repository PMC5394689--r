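#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted p-values by the step-up rule: sort ascending, set
#' `adj_(i) = min_{j >= i} p_(j) * m / j`, cap at 1, and map back to the
#' input order. Monotone: a smaller raw p never receives a larger adjusted
#' value.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stopf("all p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) {
    return(numeric(0))
  }
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(ranked))) # running min over j >= i
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

#' Trend tests of flux ratios against a condition covariate
#'
#' For each of the 13 branch-point flux ratios, averages the replicate
#' measurements within each condition and fits an ordinary least-squares
#' regression of the mean ratio on the covariate: sodium concentration (mM),
#' log-transformed magnesium concentration (natural log; magnesium spans
#' orders of magnitude), or doubling time (minutes). The slope's two-sided
#' t-test p-values are FDR-adjusted across the 13 ratios with [bh_fdr()].
#' A ratio with zero variance across conditions gets slope 0 and p = 1 by
#' convention.
#'
#' @param flux A `flux_table` from [read_flux_table()] / [flux_table()]. For
#'   the doubling-time covariate the table must carry a `doubling_time_min`
#'   column.
#' @param covariate One of `"na_mM"`, `"log_mg_mM"`, `"doubling_time_min"`.
#' @return A `flux_regression` data.frame with one row per ratio: `ratio_name`,
#'   `covariate`, `slope`, `intercept`, `p_value`, `p_adjusted`, `n`.
#' @export
regress_flux <- function(flux, covariate = c("na_mM", "log_mg_mM", "doubling_time_min")) {
  covariate <- match.arg(covariate)
  src_col <- switch(covariate,
    na_mM = "na_mM",
    log_mg_mM = "mg_mM",
    doubling_time_min = "doubling_time_min"
  )
  if (!src_col %in% names(flux)) {
    stopf("flux table has no '%s' column (needed for covariate '%s')", src_col, covariate)
  }
  # replicate-averaged value per condition and ratio
  agg <- stats::aggregate(
    flux[, c("value", src_col)],
    by = list(condition_id = flux$condition_id, ratio_name = flux$ratio_name),
    FUN = mean
  )
  if (covariate == "log_mg_mM") {
    if (any(agg[[src_col]] <= 0)) stopf("mg_mM must be > 0 for the log transform")
    agg$x <- log(agg[[src_col]])
  } else {
    agg$x <- agg[[src_col]]
  }
  rows <- lapply(split(agg, agg$ratio_name), function(d) {
    x <- d$x
    y <- d$value
    n <- length(x)
    if (length(unique(x)) < 3L) {
      stopf(
        "ratio '%s' has %d distinct covariate values; need >= 3",
        d$ratio_name[1L], length(unique(x))
      )
    }
    if (stats::var(x) == 0) stopf("zero covariate variance for ratio '%s'", d$ratio_name[1L])
    if (stats::var(y) == 0) {
      # flat response: no trend by construction
      return(data.frame(
        ratio_name = d$ratio_name[1L], covariate = covariate,
        slope = 0, intercept = y[1L], p_value = 1, n = n,
        stringsAsFactors = FALSE
      ))
    }
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)$coefficients
    data.frame(
      ratio_name = d$ratio_name[1L], covariate = covariate,
      slope = sm["x", "Estimate"], intercept = sm["(Intercept)", "Estimate"],
      p_value = sm["x", "Pr(>|t|)"], n = n,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- bh_fdr(out$p_value)
  out <- out[, c(
    "ratio_name", "covariate", "slope", "intercept",
    "p_value", "p_adjusted", "n"
  )]
  class(out) <- c("flux_regression", "data.frame")
  out
}
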