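#' Replicate-consistency quality control
#'
#' Compares two replicate samples by the distribution of per-gene log2 count
#' differences. Under pure measurement noise this distribution should be
#' centred at zero and roughly bell-shaped; a shifted median indicates a
#' systematic difference (e.g. a depth or preparation artefact). Only genes
#' detected (count > 0) in both samples enter the comparison.
#'
#' @param a,b Nonnegative count vectors for the two samples, same gene order
#'   (columns of a [count_matrix()]).
#' @param flag_threshold Flag the pair when the absolute median log2
#'   difference exceeds this value. Default 0.5 (a sustained ~1.4-fold shift).
#' @param ids Optional length-2 character vector naming the two samples.
#' @return A `qc_report` list with the median, IQR and skewness of the log2
#'   differences, the number of co-detected genes, and the flag.
#' @export
check_replicate_consistency <- function(a, b, flag_threshold = 0.5, ids = c("a", "b")) {
  assert_scalar_number(flag_threshold, "flag_threshold", positive = TRUE)
  if (length(a) != length(b)) stopf("`a` and `b` must have equal length")
  keep <- a > 0 & b > 0
  n_codetected <- sum(keep)
  if (n_codetected < 50L) {
    stopf(
      "only %d genes detected in both samples; need >= 50 for an informative histogram",
      n_codetected
    )
  }
  ld <- log2(a[keep]) - log2(b[keep])
  med <- stats::median(ld)
  flag <- abs(med) > flag_threshold
  structure(
    list(
      sample_a = ids[1L],
      sample_b = ids[2L],
      n_codetected = n_codetected,
      median_log2_diff = med,
      iqr_log2_diff = stats::IQR(ld),
      skewness_log2_diff = moment_skewness(ld),
      flag_threshold = flag_threshold,
      flagged = flag,
      note = if (flag) {
        sprintf("median log2 difference %.3f exceeds threshold %.3f", med, flag_threshold)
      } else {
        "consistent"
      }
    ),
    class = "qc_report"
  )
}

#' Run replicate QC across all replicate pairs of a dataset
#'
#' Pairs samples sharing growth phase, carbon source, ion levels and omics
#' kind (all metadata columns except batch/replicate/time), and runs
#' [check_replicate_consistency()] on every within-condition pair.
#'
#' @param counts A [count_matrix()].
#' @param meta A matching `sample_table`.
#' @param flag_threshold Passed through.
#' @return A list of `qc_report` objects (possibly empty).
#' @export
qc_all_replicates <- function(counts, meta, flag_threshold = 0.5) {
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  cond <- paste(meta$growth_phase, meta$carbon_source, meta$na_mM, meta$mg_mM)
  reports <- list()
  for (grp in split(seq_len(ncol(counts)), cond)) {
    if (length(grp) < 2L) next
    pairs <- utils::combn(grp, 2L)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]
      j <- pairs[2L, k]
      rep_k <- tryCatch(
        check_replicate_consistency(
          counts[, i], counts[, j],
          flag_threshold = flag_threshold,
          ids = colnames(counts)[c(i, j)]
        ),
        error = function(e) NULL # pair with too few co-detected genes
      )
      if (!is.null(rep_k)) reports[[length(reports) + 1L]] <- rep_k
    }
  }
  reports
}

#' Median-of-ratios size factors with a +1 pseudocount
#'
#' Computes per-sample scaling factors by the median-of-ratios method on the
#' pseudocounted matrix: a pseudocount of +1 is added to every cell (so genes
#' with zeros in some samples still contribute), the reference for each gene
#' is the geometric mean of its pseudocounted counts across samples, and each
#' sample's factor is the median over genes of (count + 1) / reference. The
#' factors are intended to divide the *raw* counts (see
#' [normalize_counts()]); the pseudocount is used only while estimating them.
#'
#' @param m A [count_matrix()] (or any nonnegative numeric matrix with
#'   dimnames).
#' @return A `data.frame` with columns `sample_id` and `factor`.
#' @export
compute_size_factors <- function(m) {
  if (!is.matrix(m) || nrow(m) < 1L || ncol(m) < 1L) {
    stopf("`m` must be a nonempty matrix")
  }
  pc <- unclass(m) + 1
  ref <- exp(rowMeans(log(pc))) # geometric mean per gene; finite since pc >= 1
  factors <- apply(pc, 2L, function(col) stats::median(col / ref))
  bad <- which(!is.finite(factors) | factors <= 0)
  if (length(bad)) {
    stopf("degenerate size factor for sample(s): %s", toString(colnames(m)[bad]))
  }
  data.frame(
    sample_id = colnames(m), factor = unname(factors),
    stringsAsFactors = FALSE
  )
}

#' Divide raw counts by their size factors
#'
#' @param m A [count_matrix()] or numeric matrix (raw counts, without
#'   pseudocounts).
#' @param f Size factors as returned by [compute_size_factors()].
#' @return A real-valued matrix of normalized counts, same dimnames as `m`.
#' @export
normalize_counts <- function(m, f) {
  idx <- match(colnames(m), f$sample_id)
  if (anyNA(idx)) {
    stopf("no size factor for sample(s): %s", toString(colnames(m)[is.na(idx)]))
  }
  out <- sweep(unclass(m), 2L, f$factor[idx], "/")
  class(out) <- c("matrix", "array")
  attr(out, "omics_kind") <- NULL
  out
}

#' Logarithmic transformation with a pseudocount
#'
#' Elementwise `log_base(value + pseudocount)`; strictly monotone in the
#' input. The package default for clustering input is base 2 with
#' pseudocount 1, so a zero count maps to 0.
#'
#' @param m Nonnegative numeric matrix (normalized counts).
#' @param pseudocount Positive offset added before the log. Default 1.
#' @param base Logarithm base > 1. Default 2.
#' @return Transformed matrix.
#' @export
log_transform <- function(m, pseudocount = 1, base = 2) {
  assert_scalar_number(pseudocount, "pseudocount", positive = TRUE)
  assert_scalar_number(base, "base")
  if (base <= 1) stopf("`base` must be > 1")
  if (anyNA(m) || any(m < 0)) {
    stopf("`m` must be nonnegative with no missing values")
  }
  log(m + pseudocount, base = base)
}
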