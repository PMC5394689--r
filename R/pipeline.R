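#' Build a validated pipeline configuration
#'
#' One flat configuration drives the whole analysis. Data enter either from
#' files (`counts` + `metadata` TSV paths) or from the simulator
#' (`simulate_preset`). The seed is mandatory: every stochastic stage
#' (simulation, permutations) derives from it and is echoed into the outputs.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed, mandatory.
#' @param counts,metadata Paths to input TSVs (alternative to simulation).
#' @param omics_kind Omics kind of the count input.
#' @param simulate_preset `"mrna-like"`, `"protein-like"` or `"null"` to
#'   generate the input instead of reading it.
#' @param n_genes Genes for the simulated input.
#' @param pseudocount,log_base Log-transform parameters (defaults 1 and 2).
#' @param linkage Only `"complete"` is supported.
#' @param n_perm,variables,binning Permutation-test parameters (see
#'   [run_all_variables()]).
#' @param qc_threshold Replicate-QC flag threshold.
#' @param growth,flux Optional paths to growth-curve / flux-ratio TSVs.
#' @param flux_covariate Covariate for the flux regressions.
#' @param fdr_q FDR significance threshold echoed in the outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed,
                            counts = NULL, metadata = NULL,
                            omics_kind = "mrna",
                            simulate_preset = NULL, n_genes = 1000L,
                            pseudocount = 1, log_base = 2,
                            linkage = "complete",
                            n_perm = 10000L,
                            variables = c(
                              "growth_phase", "carbon_source",
                              "mg_level", "na_level", "batch"
                            ),
                            binning = default_binning(),
                            qc_threshold = 0.5,
                            growth = NULL, flux = NULL,
                            flux_covariate = "doubling_time_min",
                            fdr_q = 0.05) {
  if (missing(seed) || is.null(seed)) {
    stopf("pipeline config requires a `seed`")
  }
  if (is.null(simulate_preset) && (is.null(counts) || is.null(metadata))) {
    stopf("config needs either `simulate_preset` or both `counts` and `metadata`")
  }
  if (!identical(linkage, "complete")) {
    stopf("only complete linkage is supported (got '%s')", linkage)
  }
  for (p in c(counts, metadata, growth, flux)) {
    if (!is.null(p) && !file.exists(p)) stopf("input file not found: %s", p)
  }
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed),
      counts = counts, metadata = metadata, omics_kind = omics_kind,
      simulate_preset = simulate_preset, n_genes = as.integer(n_genes),
      pseudocount = pseudocount, log_base = log_base, linkage = linkage,
      n_perm = as.integer(n_perm), variables = variables, binning = binning,
      qc_threshold = qc_threshold, growth = growth, flux = flux,
      flux_covariate = flux_covariate, fdr_q = fdr_q
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a flat JSON file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error. `overrides` (e.g. parsed CLI flags) take precedence over file
#' values.
#'
#' @param path Path to the JSON config.
#' @param overrides Named list of overriding values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), c(known, "binning"))
  if (length(unknown)) stopf("unknown config key(s): %s", toString(unknown))
  if (!is.null(vals$binning)) vals$binning <- do.call(default_binning, as.list(vals$binning))
  do.call(pipeline_config, vals)
}

pipeline_log <- function(fmt, ...) {
  message(sprintf("[omicsclust %s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

#' Run the full condition-clustering pipeline
#'
#' Executes read/simulate, replicate QC, size factors, normalization, log
#' transform, sample distances, complete linkage, cophenetic matrix, and the
#' permutation z-score test for every configured variable; optionally also
#' the doubling-time and flux-regression stages. Every intermediate artifact
#' is written under `cfg$out_dir`, and a `manifest.json` records the
#' artifact list with MD5 checksums, the seed, and package/R versions.
#' Rerunning with the same config and seed reproduces every artifact
#' byte-for-byte.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  emit <- function(name) {
    artifacts[[length(artifacts) + 1L]] <<- file.path(cfg$out_dir, name)
    file.path(cfg$out_dir, name)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    pipeline_log("stage %-12s done in %.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  dat <- stage("input", {
    if (!is.null(cfg$simulate_preset)) {
      sim <- simulate_counts(preset_design(cfg$simulate_preset,
        n_genes = cfg$n_genes, seed = cfg$seed
      ))
      list(counts = sim$counts, meta = sim$samples)
    } else {
      counts <- read_count_matrix(cfg$counts, cfg$omics_kind)
      meta <- read_sample_table(cfg$metadata, counts = counts)
      list(counts = counts, meta = meta)
    }
  })
  pipeline_log(
    "input: %d genes x %d samples (%s)",
    nrow(dat$counts), ncol(dat$counts), attr(dat$counts, "omics_kind")
  )
  write_matrix_tsv(dat$counts, emit("counts.tsv"))
  utils::write.table(dat$meta, emit("metadata.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  qc <- stage("qc", qc_all_replicates(dat$counts, dat$meta, cfg$qc_threshold))
  writeLines(
    jsonlite::toJSON(
      list(
        schema_version = 1L, type = "qc_report_set",
        n_pairs = length(qc), n_flagged = sum(vapply(qc, `[[`, logical(1), "flagged")),
        reports = lapply(qc, unclass)
      ),
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
    ),
    emit("qc.json")
  )

  sf <- stage("sizefactors", compute_size_factors(dat$counts))
  utils::write.table(sf, emit("size_factors.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  norm <- stage("normalize", normalize_counts(dat$counts, sf))
  write_matrix_tsv(norm, emit("normalized.tsv"))
  logm <- stage("log", log_transform(norm, cfg$pseudocount, cfg$log_base))
  write_matrix_tsv(logm, emit("log_normalized.tsv"))

  tree <- stage("cluster", complete_linkage(sample_distances(logm)))
  to_newick(tree, emit("dendrogram.nwk"))
  C <- stage("cophenetic", cophenetic_matrix(tree))
  write_matrix_tsv(C, emit("cophenetic.tsv"), id_col = "sample_id")

  sig <- stage("permtest", run_all_variables(
    C, dat$meta,
    variables = cfg$variables, bins = cfg$binning,
    n_perm = cfg$n_perm, seed = cfg$seed
  ))
  write_results(sig, emit("permtest.json"))

  if (!is.null(cfg$growth)) {
    dt <- stage("growth", estimate_doubling_times(read_growth_curves(cfg$growth)))
    write_results(dt, emit("doubling.json"))
  }
  if (!is.null(cfg$flux)) {
    fx <- stage("flux", regress_flux(read_flux_table(cfg$flux), cfg$flux_covariate))
    write_results(fx, emit("flux_regression.json"))
  }

  manifest <- list(
    schema_version = 1L,
    package = "omicsclust",
    package_version = as.character(utils::packageVersion("omicsclust")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    n_perm = cfg$n_perm,
    artifacts = data.frame(
      name = basename(unlist(artifacts)),
      md5 = unname(tools::md5sum(unlist(artifacts))),
      stringsAsFactors = FALSE
    )
  )
  writeLines(
    jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    file.path(cfg$out_dir, "manifest.json")
  )
  pipeline_log("wrote %d artifacts + manifest to %s", length(artifacts), cfg$out_dir)
  invisible(manifest)
}
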