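#' Mean cophenetic distance among same-label sample pairs
#'
#' For a categorical labelling of the dendrogram leaves, computes the mean
#' cophenetic distance over unordered sample pairs sharing a label. For a
#' single `level`, only pairs within that level count; for `"overall"`, the
#' pair sets of every level are pooled (pair-weighted) before averaging.
#'
#' @param C A `cophenetic_matrix` from [cophenetic_matrix()].
#' @param labels Character/factor vector of labels, aligned with the rows of
#'   `C` (or named by sample id).
#' @param level One level of `labels`, or `"overall"`.
#' @return A list with `mean` and `n_pairs`.
#' @export
mean_within_label_distance <- function(C, labels, level = "overall") {
  labels <- align_labels(C, labels)
  if (level != "overall" && !level %in% labels) {
    stopf("level '%s' not present in labels", level)
  }
  lv <- if (level == "overall") unique(labels) else level
  tot <- 0
  np <- 0L
  for (l in lv) {
    idx <- which(labels == l)
    if (length(idx) < 2L) {
      if (level != "overall") {
        stopf("level '%s' has %d sample(s); need >= 2 for any pair", l, length(idx))
      }
      next
    }
    tot <- tot + sum(C[idx, idx]) / 2
    np <- np + (length(idx) * (length(idx) - 1L)) %/% 2L
  }
  if (np == 0L) stopf("no same-label pair exists for level '%s'", level)
  list(mean = tot / np, n_pairs = np)
}

align_labels <- function(C, labels) {
  if (!is.null(names(labels))) {
    idx <- match(rownames(C), names(labels))
    if (anyNA(idx)) {
      stopf("labels missing for sample(s): %s", toString(rownames(C)[is.na(idx)]))
    }
    labels <- labels[idx]
  }
  if (length(labels) != nrow(C)) {
    stopf("labels length %d does not match %d samples", length(labels), nrow(C))
  }
  as.character(labels)
}

# Per-level pair sums/counts and the pooled statistic, one pass.
# Returns c(overall, per-level means); NA where a level has < 2 samples.
within_label_stats <- function(C, labels, levels) {
  sums <- numeric(length(levels))
  pairs <- integer(length(levels))
  for (k in seq_along(levels)) {
    idx <- which(labels == levels[k])
    m <- length(idx)
    if (m >= 2L) {
      sums[k] <- sum(C[idx, idx]) / 2
      pairs[k] <- (m * (m - 1L)) %/% 2L
    }
  }
  overall <- if (sum(pairs) > 0L) sum(sums) / sum(pairs) else NA_real_
  means <- ifelse(pairs > 0L, sums / pmax(pairs, 1L), NA_real_)
  list(overall = overall, level_means = means, n_pairs = pairs)
}

#' Permutation z-score test for clustering by a categorical variable
#'
#' Quantifies whether samples sharing a label sit closer together in the
#' dendrogram than expected by chance. The observed statistic is the mean
#' cophenetic distance over same-label pairs (pooled across levels for the
#' `"overall"` row, and within each level for the per-level rows). The null
#' is generated by repeatedly reshuffling the whole label vector uniformly at
#' random (the label multiset is preserved) and recomputing the statistic;
#' the z-score is `(observed - null mean) / null sd` with the n-1 sample
#' standard deviation. Negative z means tighter-than-random clustering; the
#' conventional significance flag is `z < -1.96`.
#'
#' @param C A `cophenetic_matrix`.
#' @param labels Label vector aligned with `C` (or named by sample id).
#' @param n_perm Number of permutations, >= 100. Default 10000.
#' @param seed Integer seed for the permutation stream (mandatory;
#'   recorded in the result).
#' @param variable_name Name stored in the result rows.
#' @param overall_method `"pooled"` (default) pools all same-label pairs into
#'   one pair set; `"level_mean"` averages the per-level means instead.
#' @return A `cluster_significance` data.frame: one `"overall"` row plus one
#'   row per level, with columns `variable`, `level`, `observed_mean`,
#'   `null_mean`, `null_sd`, `z`, `undefined`, `significant`, `n_samples`,
#'   `n_pairs`, `n_perm`, `seed`. `undefined` marks statistics invariant
#'   under permutation (zero null spread) or levels with no pairs; their `z`
#'   is `NA`.
#' @export
permutation_z <- function(C, labels, n_perm = 10000L, seed,
                          variable_name = "variable",
                          overall_method = c("pooled", "level_mean")) {
  overall_method <- match.arg(overall_method)
  if (missing(seed)) stopf("`seed` is mandatory")
  if (!is.numeric(n_perm) || n_perm < 100L) stopf("`n_perm` must be >= 100")
  n_perm <- as.integer(n_perm)
  labels <- align_labels(C, labels)
  n <- nrow(C)
  levels <- sort(unique(labels))
  level_sizes <- vapply(levels, function(l) sum(labels == l), integer(1))
  if (!any(level_sizes >= 2L)) {
    stopf("no level has >= 2 samples; the statistic has no pairs")
  }
  obs <- within_label_stats(C, labels, levels)
  obs_overall <- if (overall_method == "pooled") {
    obs$overall
  } else {
    mean(obs$level_means, na.rm = TRUE)
  }

  null_overall <- numeric(n_perm)
  null_levels <- matrix(NA_real_, n_perm, length(levels))
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      perm <- within_label_stats(C, labels[sample.int(n)], levels)
      null_overall[p] <- if (overall_method == "pooled") {
        perm$overall
      } else {
        mean(perm$level_means, na.rm = TRUE)
      }
      null_levels[p, ] <- perm$level_means
    }
  })

  mk_row <- function(level, observed, null_values, n_samples, n_pairs) {
    if (is.na(observed)) {
      return(data.frame(
        variable = variable_name, level = level, observed_mean = NA_real_,
        null_mean = NA_real_, null_sd = NA_real_, z = NA_real_,
        undefined = TRUE, significant = FALSE, n_samples = n_samples,
        n_pairs = n_pairs, n_perm = n_perm, seed = as.integer(seed),
        stringsAsFactors = FALSE
      ))
    }
    mu <- mean(null_values)
    sdv <- stats::sd(null_values)
    undef <- !is.finite(sdv) || sdv == 0
    z <- if (undef) NA_real_ else (observed - mu) / sdv
    data.frame(
      variable = variable_name, level = level, observed_mean = observed,
      null_mean = mu, null_sd = if (undef) 0 else sdv, z = z,
      undefined = undef, significant = isTRUE(z < -1.96),
      n_samples = n_samples, n_pairs = n_pairs, n_perm = n_perm,
      seed = as.integer(seed), stringsAsFactors = FALSE
    )
  }

  rows <- list(mk_row(
    "overall", obs_overall, null_overall, n,
    sum(obs$n_pairs)
  ))
  for (k in seq_along(levels)) {
    rows[[length(rows) + 1L]] <- mk_row(
      levels[k], obs$level_means[k], null_levels[, k],
      level_sizes[k], obs$n_pairs[k]
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cluster_significance", "data.frame")
  attr(out, "overall_method") <- overall_method
  out
}

#' Default binning of numeric design variables into categorical levels
#'
#' Ion concentrations are recorded in mM but tested as categorical levels:
#' sodium is split at `na_high_min` into base vs high, and magnesium into
#' low / base / high around the reference medium concentration `mg_base`
#' (with relative tolerance `mg_tol` for float-safe equality).
#'
#' @param na_high_min Sodium concentrations at or above this are "high_na"
#'   (default 100 mM; the reference medium carries 5 mM).
#' @param mg_base Reference magnesium concentration (default 0.8 mM).
#' @param mg_tol Relative tolerance for calling a concentration "base".
#' @param collapse_phase If TRUE, stationary and late stationary collapse
#'   into one "stationary" level (two-level phase contrast).
#' @return A named list consumed by [variable_labels()] /
#'   [run_all_variables()].
#' @export
default_binning <- function(na_high_min = 100, mg_base = 0.8, mg_tol = 1e-6,
                            collapse_phase = FALSE) {
  list(
    na_high_min = na_high_min, mg_base = mg_base, mg_tol = mg_tol,
    collapse_phase = collapse_phase
  )
}

#' Categorical labels for one design variable
#'
#' Maps a metadata column to the categorical labelling used by the
#' permutation test: `na_level` and `mg_level` are binned from the numeric
#' concentrations, `growth_phase` optionally collapses the stationary
#' phases, any other variable must be a metadata column and is used as-is.
#'
#' @param meta A `sample_table`.
#' @param variable Variable name.
#' @param bins A binning config from [default_binning()].
#' @return Character vector of labels named by sample id.
#' @export
variable_labels <- function(meta, variable, bins = default_binning()) {
  labels <- switch(variable,
    na_level = ifelse(meta$na_mM >= bins$na_high_min, "high_na", "base_na"),
    mg_level = {
      rel <- abs(meta$mg_mM - bins$mg_base) / bins$mg_base
      ifelse(rel <= bins$mg_tol, "base_mg",
        ifelse(meta$mg_mM > bins$mg_base, "high_mg", "low_mg")
      )
    },
    growth_phase = {
      ph <- as.character(meta$growth_phase)
      if (isTRUE(bins$collapse_phase)) {
        ifelse(ph == "exponential", "exponential", "stationary")
      } else {
        ph
      }
    },
    {
      if (!variable %in% names(meta)) {
        stopf("variable '%s' is not a metadata column", variable)
      }
      as.character(meta[[variable]])
    }
  )
  names(labels) <- meta$sample_id
  labels
}

#' Clustering significance for every design variable
#'
#' Runs [permutation_z()] for each requested variable against one sample
#' dendrogram, returning a single stacked table with one overall row and one
#' row per level for each variable. Sample order is canonicalized to the
#' cophenetic matrix, and each variable uses a seed derived deterministically
#' from `seed` and the variable's name (alphabetical rank), so results are
#' invariant to metadata row order and to the order of `variables`.
#'
#' @param C A `cophenetic_matrix`.
#' @param meta A `sample_table` covering the samples of `C`.
#' @param variables Variables to test. Defaults to the five standard design
#'   variables.
#' @param bins Binning config, see [default_binning()].
#' @param n_perm,overall_method Passed to [permutation_z()].
#' @param seed Integer base seed (mandatory).
#' @return A `cluster_significance` data.frame.
#' @export
run_all_variables <- function(C, meta,
                              variables = c(
                                "growth_phase", "carbon_source",
                                "mg_level", "na_level", "batch"
                              ),
                              bins = default_binning(), n_perm = 10000L, seed,
                              overall_method = c("pooled", "level_mean")) {
  overall_method <- match.arg(overall_method)
  if (missing(seed)) stopf("`seed` is mandatory")
  idx <- match(rownames(C), meta$sample_id)
  if (anyNA(idx)) {
    stopf("metadata missing for sample(s): %s", toString(rownames(C)[is.na(idx)]))
  }
  meta <- meta[idx, , drop = FALSE]
  out <- lapply(variables, function(v) {
    labels <- variable_labels(meta, v, bins)
    seed_v <- as.integer(seed) + match(v, sort(variables))
    permutation_z(C, labels,
      n_perm = n_perm, seed = seed_v,
      variable_name = v, overall_method = overall_method
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cluster_significance", "data.frame")
  attr(res, "overall_method") <- overall_method
  attr(res, "base_seed") <- as.integer(seed)
  res
}
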