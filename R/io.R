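#' Controlled vocabularies for sample annotations
#'
#' Growth phases and carbon sources accepted in sample metadata, and the
#' default vocabulary of the 13 central-metabolism flux-ratio labels. Flux
#' ratio names are free strings validated against a user-replaceable list, so
#' analyses using a different branch-point naming scheme can pass their own
#' vocabulary to [read_flux_table()].
#'
#' @return Character vector of allowed values.
#' @export
growth_phases <- function() c("exponential", "stationary", "late_stationary")

#' @rdname growth_phases
#' @export
carbon_sources <- function() c("glucose", "glycerol", "lactate", "gluconate")

#' @rdname growth_phases
#' @export
default_flux_ratio_names <- function() {
  c(
    "serine_from_glycolysis",
    "pyruvate_from_ed_pathway_ub",
    "pyruvate_from_malate_ub",
    "pyruvate_from_malate_lb",
    "pep_from_oxaloacetate",
    "oxaloacetate_from_pep",
    "oxaloacetate_from_glyoxylate",
    "pep_through_transketolase",
    "pentose_5_phosphate_from_g6p",
    "erythrose_4_phosphate_from_pentose_5_phosphate",
    "glycine_from_serine",
    "glycine_from_co2_thf",
    "acetyl_coa_from_pyruvate"
  )
}

#' Construct a validated count matrix
#'
#' A `count_matrix` is a nonnegative integer gene-by-sample matrix with unique
#' gene and sample identifiers and an omics kind (`"mrna"` for read counts,
#' `"protein"` for spectral counts).
#'
#' @param counts Numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param omics_kind `"mrna"` or `"protein"`.
#' @return An object of class `count_matrix` (an integer-valued matrix with an
#'   `omics_kind` attribute).
#' @export
count_matrix <- function(counts, omics_kind = c("mrna", "protein")) {
  omics_kind <- match.arg(omics_kind)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stopf("`counts` must be a numeric matrix")
  }
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stopf("`counts` must have rownames (gene ids) and colnames (sample ids)")
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) stopf("duplicate gene id(s): %s", toString(dup_g))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) stopf("duplicate sample id(s): %s", toString(dup_s))
  if (anyNA(counts)) stopf("`counts` contains missing values")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stopf(
      "negative count at gene '%s', sample '%s'",
      gene_ids[neg[1L, 1L]], sample_ids[neg[1L, 2L]]
    )
  }
  nonint <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(nonint)) {
    stopf(
      "non-integral count %g at gene '%s', sample '%s'",
      counts[nonint[1L, , drop = FALSE]],
      gene_ids[nonint[1L, 1L]], sample_ids[nonint[1L, 2L]]
    )
  }
  storage.mode(counts) <- "double" # avoid integer overflow on large counts
  counts <- round(counts)
  structure(counts, omics_kind = omics_kind, class = c("count_matrix", "matrix", "array"))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %d genes x %d samples (%s)\n",
    nrow(x), ncol(x), attr(x, "omics_kind")
  ))
  invisible(x)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' The file must be tab-delimited with a header row of sample ids and a first
#' column `gene_id`. Protein spectral counts may be fractional (shared
#' peptides are split across proteins): they are rounded to the nearest
#' integer, half away from zero, and blank cells (unobserved proteins) become
#' zero. mRNA counts must already be integral; a fractional mRNA cell is an
#' error.
#'
#' @param path Path to the TSV file.
#' @param omics_kind `"mrna"` or `"protein"`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, omics_kind = c("mrna", "protein")) {
  omics_kind <- match.arg(omics_kind)
  if (!file.exists(path)) stopf("count file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("count TSV needs a gene_id column plus >= 1 sample")
  gene_ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric cell in count matrix %s", path)
  rownames(m) <- gene_ids
  if (anyNA(m)) {
    if (omics_kind == "protein") {
      m[is.na(m)] <- 0 # unobserved proteins carry zero counts
    } else {
      na_at <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stopf(
        "missing mRNA count at gene '%s', sample '%s'",
        rownames(m)[na_at[1L]], colnames(m)[na_at[2L]]
      )
    }
  }
  if (omics_kind == "protein") {
    m <- round_half_away(m)
  } else {
    nonint <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)
    if (nrow(nonint)) {
      stopf(
        "non-integral mRNA count %g at gene '%s', sample '%s'",
        m[nonint[1L, , drop = FALSE]],
        rownames(m)[nonint[1L, 1L]], colnames(m)[nonint[1L, 2L]]
      )
    }
  }
  count_matrix(m, omics_kind)
}

#' Read and validate a sample metadata table
#'
#' Expects a tab-delimited file with columns `sample_id`, `growth_phase`,
#' `carbon_source`, `na_mM`, `mg_mM`, `batch`, `replicate`, and optionally
#' `omics_kind` and `time_h` (hours post-inoculation, for time courses).
#' Growth phase and carbon source are validated against [growth_phases()] and
#' [carbon_sources()]; ion concentrations must be positive.
#'
#' @param path Path to the metadata TSV.
#' @param counts Optional [count_matrix()]; if supplied, the metadata sample
#'   ids must match the matrix sample ids exactly (orphans on either side are
#'   an error).
#' @return A `data.frame` of class `sample_table`.
#' @export
read_sample_table <- function(path, counts = NULL) {
  if (!file.exists(path)) stopf("metadata file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_table(df, counts = counts)
}

#' @rdname read_sample_table
#' @param df A data.frame with the columns described above (in-memory
#'   construction path used by the simulators).
#' @export
sample_table <- function(df, counts = NULL) {
  required <- c(
    "sample_id", "growth_phase", "carbon_source",
    "na_mM", "mg_mM", "batch", "replicate"
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stopf("metadata is missing column(s): %s", toString(missing_cols))
  }
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stopf("duplicate sample id(s) in metadata: %s", toString(dup))
  bad_phase <- setdiff(unique(df$growth_phase), growth_phases())
  if (length(bad_phase)) {
    stopf(
      "unknown growth_phase value(s): %s (allowed: %s)",
      toString(bad_phase), toString(growth_phases())
    )
  }
  bad_carbon <- setdiff(unique(df$carbon_source), carbon_sources())
  if (length(bad_carbon)) {
    stopf(
      "unknown carbon_source value(s): %s (allowed: %s)",
      toString(bad_carbon), toString(carbon_sources())
    )
  }
  for (col in c("na_mM", "mg_mM")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v <= 0)) {
      stopf("`%s` must be positive and non-missing for every sample", col)
    }
  }
  if ("omics_kind" %in% names(df)) {
    bad <- setdiff(unique(df$omics_kind), c("mrna", "protein"))
    if (length(bad)) stopf("unknown omics_kind value(s): %s", toString(bad))
  }
  df$batch <- as.character(df$batch)
  df$replicate <- as.character(df$replicate)
  if (!is.null(counts)) {
    ids <- colnames(counts)
    extra <- setdiff(df$sample_id, ids)
    absent <- setdiff(ids, df$sample_id)
    if (length(extra) || length(absent)) {
      stopf(
        "sample id mismatch vs count matrix%s%s",
        if (length(extra)) paste0("; metadata-only: ", toString(extra)) else "",
        if (length(absent)) paste0("; counts-only: ", toString(absent)) else ""
      )
    }
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Construct a validated growth curve
#'
#' Timed OD600 absorbance readings for one biological replicate grown under
#' one condition. At least 4 points are required, times must be strictly
#' increasing, and all readings must be positive.
#'
#' @param replicate_id,condition_id Identifier strings.
#' @param time_min Numeric vector of sampling times, minutes, strictly
#'   increasing.
#' @param od600 Positive absorbance readings, same length as `time_min`.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(replicate_id, condition_id, time_min, od600) {
  if (length(time_min) != length(od600)) {
    stopf("time_min and od600 must have equal length")
  }
  if (length(time_min) < 4L) stopf("growth curve needs >= 4 points")
  if (anyNA(time_min) || anyNA(od600)) stopf("growth curve contains NA")
  if (any(diff(time_min) <= 0)) stopf("time_min must be strictly increasing")
  if (any(od600 <= 0)) stopf("all od600 readings must be > 0")
  structure(
    list(
      replicate_id = as.character(replicate_id),
      condition_id = as.character(condition_id),
      time_min = as.numeric(time_min),
      od600 = as.numeric(od600)
    ),
    class = "growth_curve"
  )
}

#' Read OD600 growth curves from TSV
#'
#' Expects columns `replicate_id`, `condition_id`, `time_min`, `od600`. Rows
#' are grouped by condition and replicate into one [growth_curve()] each.
#'
#' @param path Path to the growth TSV.
#' @return A list of `growth_curve` objects.
#' @export
read_growth_curves <- function(path) {
  if (!file.exists(path)) stopf("growth file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("replicate_id", "condition_id", "time_min", "od600")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stopf("growth TSV missing column(s): %s", toString(missing_cols))
  }
  key <- paste(df$condition_id, df$replicate_id, sep = "\r")
  lapply(split(df, key), function(g) {
    g <- g[order(g$time_min), , drop = FALSE]
    growth_curve(g$replicate_id[1L], g$condition_id[1L], g$time_min, g$od600)
  })
}

#' Read and validate a flux-ratio table
#'
#' Expects columns `sample_id`, `condition_id`, `replicate`, `na_mM`, `mg_mM`,
#' `ratio_name`, `value`, and optionally `doubling_time_min`. Values are split
#' ratios in `[0, 1]`; `ratio_name` is validated against a 13-name vocabulary.
#'
#' @param path Path to the flux TSV.
#' @param ratio_names Allowed ratio names (defaults to
#'   [default_flux_ratio_names()]).
#' @return A `data.frame` of class `flux_table`.
#' @export
read_flux_table <- function(path, ratio_names = default_flux_ratio_names()) {
  if (!file.exists(path)) stopf("flux file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  flux_table(df, ratio_names = ratio_names)
}

#' @rdname read_flux_table
#' @param df In-memory data.frame with the columns above.
#' @export
flux_table <- function(df, ratio_names = default_flux_ratio_names()) {
  required <- c(
    "sample_id", "condition_id", "replicate", "na_mM", "mg_mM",
    "ratio_name", "value"
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stopf("flux table missing column(s): %s", toString(missing_cols))
  }
  bad <- setdiff(unique(df$ratio_name), ratio_names)
  if (length(bad)) {
    stopf("unknown ratio_name value(s): %s", toString(bad))
  }
  if (!is.numeric(df$value) || anyNA(df$value) ||
    any(df$value < 0 | df$value > 1)) {
    stopf("flux ratio values must lie in [0, 1] and be non-missing")
  }
  df$replicate <- as.character(df$replicate)
  class(df) <- c("flux_table", "data.frame")
  df
}

# ---- result serialization -------------------------------------------------

RESULT_SCHEMA_VERSION <- 1L

result_type <- function(x) {
  types <- c(
    "cluster_significance", "doubling_time_estimate",
    "doubling_time_set", "flux_regression", "qc_report"
  )
  hit <- intersect(class(x), types)
  if (!length(hit)) {
    stopf(
      "write_results() supports classes %s, not %s",
      toString(types), toString(class(x))
    )
  }
  hit[1L]
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attr(x, "class") <- NULL
  }
  x
}

#' Write an analysis result object to JSON
#'
#' Serializes any of the package's result objects (cluster significance
#' tables, doubling-time estimates, flux regressions, QC reports) to a
#' versioned JSON schema at full float precision. Non-finite statistics (e.g.
#' an undefined z-score when the permutation null has zero spread) are written
#' as JSON `null` alongside an explicit flag, so the file round-trips
#' losslessly through [read_results()].
#'
#' @param results A result object produced by this package.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  type <- result_type(results)
  payload <- strip_classes(unclass(results))
  meta <- attributes(results)
  meta <- meta[setdiff(names(meta), c("class", "row.names", "names"))]
  doc <- list(
    schema_version = RESULT_SCHEMA_VERSION,
    type = type,
    meta = meta,
    payload = payload
  )
  json <- jsonlite::toJSON(
    doc,
    auto_unbox = TRUE, digits = NA, na = "null", null = "null", pretty = TRUE
  )
  ok <- tryCatch(
    {
      writeLines(json, path)
      TRUE
    },
    error = function(e) e
  )
  if (!isTRUE(ok)) stopf("cannot write results to %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Read back a result object written by [write_results()]
#'
#' @param path Path to a results JSON file.
#' @return The reconstructed result object, with its class and metadata
#'   attributes restored.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stopf("results file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = TRUE)
  if (is.null(doc$schema_version) || doc$schema_version != RESULT_SCHEMA_VERSION) {
    stopf("unsupported results schema_version in %s", path)
  }
  type <- doc$type
  payload <- doc$payload
  df_types <- c("cluster_significance", "flux_regression")
  if (type %in% df_types) {
    # columns may deserialize as lists when they contain nulls
    cols <- lapply(payload, function(col) {
      if (is.list(col)) {
        col <- vapply(col, function(v) if (is.null(v)) NA else v, numeric(1))
      }
      col
    })
    out <- as.data.frame(cols, stringsAsFactors = FALSE)
    class(out) <- c(type, "data.frame")
  } else {
    out <- payload
    if (type == "doubling_time_set") {
      out <- lapply(out, function(est) {
        est <- lapply(est, function(v) if (is.null(v)) NA else v)
        class(est) <- "doubling_time_estimate"
        est
      })
    } else {
      out <- lapply(out, function(v) if (is.null(v)) NA else v)
    }
    class(out) <- type
  }
  for (nm in names(doc$meta)) attr(out, nm) <- doc$meta[[nm]]
  out
}

#' Write a numeric matrix as TSV with a leading id column
#'
#' @param m Matrix with rownames and colnames.
#' @param path Output path.
#' @param id_col Name for the first (rowname) column.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}
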