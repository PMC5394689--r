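#' Default desk-scale experimental design table
#'
#' A balanced 48-sample design: 2 growth phases x 2 carbon sources x
#' `n_batches` batches x `n_replicates` biological replicates. Ion levels
#' vary with the replicate index (replicate 3 carries high sodium, and the
#' three replicates carry low / base / high magnesium), so every standard
#' design variable has at least two levels with two or more samples while
#' staying orthogonal to batch and condition.
#'
#' @param phases,carbons Levels used for the crossed part of the design.
#' @param n_batches,n_replicates Crossing depth. Defaults 4 and 3 (48 samples).
#' @param na_levels_mM Sodium concentration per replicate index (recycled).
#' @param mg_levels_mM Magnesium concentration per replicate index (recycled).
#' @return A `sample_table` data.frame.
#' @export
default_design_table <- function(phases = c("exponential", "stationary"),
                                 carbons = c("glucose", "glycerol"),
                                 n_batches = 4L, n_replicates = 3L,
                                 na_levels_mM = c(5, 5, 100),
                                 mg_levels_mM = c(0.08, 0.8, 8)) {
  g <- expand.grid(
    replicate = seq_len(n_replicates),
    batch = seq_len(n_batches),
    carbon_source = carbons,
    growth_phase = phases,
    stringsAsFactors = FALSE
  )
  ri <- ((g$replicate - 1L) %% length(na_levels_mM)) + 1L
  df <- data.frame(
    sample_id = sprintf("S%03d", seq_len(nrow(g))),
    growth_phase = g$growth_phase,
    carbon_source = g$carbon_source,
    na_mM = na_levels_mM[ri],
    mg_mM = mg_levels_mM[((g$replicate - 1L) %% length(mg_levels_mM)) + 1L],
    batch = paste0("B", g$batch),
    replicate = paste0("R", g$replicate),
    stringsAsFactors = FALSE
  )
  sample_table(df)
}

#' Specify a count simulation
#'
#' Counts are drawn from a negative binomial law whose log2 mean is a
#' per-gene baseline plus additive per-variable shifts: for each design
#' variable with a nonzero effect, a random fraction of genes is "affected"
#' and receives a shift of +/- `size` log2 units in each non-reference level
#' of that variable. Dispersion is the NB overdispersion (variance =
#' mu + dispersion * mu^2).
#'
#' @param n_genes Number of genes. Default 1000 (desk scale).
#' @param samples A `sample_table` design, default [default_design_table()].
#' @param effects Named list: per variable, `list(size = <log2 shift>,
#'   fraction = <affected gene fraction>)`. Variables are any accepted by
#'   [variable_labels()].
#' @param dispersion NB overdispersion, default 0.1.
#' @param baseline_mean,baseline_sd Normal law of per-gene baseline log2
#'   means, defaults 6 and 2.
#' @param omics_kind Stored on the simulated count matrix.
#' @param seed Mandatory integer seed; same seed reproduces the dataset
#'   bit-for-bit.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_genes = 1000L, samples = default_design_table(),
                              effects = list(), dispersion = 0.1,
                              baseline_mean = 6, baseline_sd = 2,
                              omics_kind = c("mrna", "protein"), seed) {
  omics_kind <- match.arg(omics_kind)
  if (missing(seed)) stopf("`seed` is mandatory")
  if (n_genes < 1L) stopf("`n_genes` must be >= 1")
  assert_scalar_number(dispersion, "dispersion", positive = TRUE)
  for (v in names(effects)) {
    e <- effects[[v]]
    if (!is.list(e) || is.null(e$size) || is.null(e$fraction)) {
      stopf("effect for '%s' must be list(size=, fraction=)", v)
    }
    if (e$fraction < 0 || e$fraction > 1) stopf("effect fraction for '%s' outside [0,1]", v)
  }
  structure(
    list(
      n_genes = as.integer(n_genes), samples = samples, effects = effects,
      dispersion = dispersion, baseline_mean = baseline_mean,
      baseline_sd = baseline_sd, omics_kind = omics_kind,
      seed = as.integer(seed)
    ),
    class = "simulation_design"
  )
}

#' Preset simulation designs
#'
#' `mrna_like_design()` plants a dominant growth-phase signal (2 log2 units
#' on 30% of genes) with weak batch and carbon effects, mirroring transcript
#' data where phase drives the clustering. `protein_like_design()` plants
#' co-dominant batch and carbon effects (each 1.0 log2 units on 30% of
#' genes) with a weak phase effect, mirroring spectral-count data where
#' technical batches and carbon source dominate the clustering while growth
#' phase barely registers. `null_design()` has no effects at all (used for
#' null calibration).
#'
#' @param n_genes,samples,seed,... Passed to [simulation_design()].
#' @return A `simulation_design`.
#' @export
mrna_like_design <- function(n_genes = 1000L, samples = default_design_table(),
                             seed, ...) {
  simulation_design(
    n_genes = n_genes, samples = samples,
    effects = list(
      growth_phase = list(size = 2.0, fraction = 0.30),
      batch = list(size = 0.2, fraction = 0.10),
      carbon_source = list(size = 0.2, fraction = 0.05)
    ),
    omics_kind = "mrna", seed = seed, ...
  )
}

#' @rdname mrna_like_design
#' @export
protein_like_design <- function(n_genes = 1000L, samples = default_design_table(),
                                seed, ...) {
  simulation_design(
    n_genes = n_genes, samples = samples,
    effects = list(
      batch = list(size = 1.0, fraction = 0.30),
      carbon_source = list(size = 1.0, fraction = 0.30),
      growth_phase = list(size = 0.2, fraction = 0.05)
    ),
    omics_kind = "protein", seed = seed, ...
  )
}

#' @rdname mrna_like_design
#' @export
null_design <- function(n_genes = 1000L, samples = default_design_table(),
                        seed, ...) {
  simulation_design(
    n_genes = n_genes, samples = samples, effects = list(),
    seed = seed, ...
  )
}

#' @rdname mrna_like_design
#' @param preset One of `"mrna-like"`, `"protein-like"`, `"null"`.
#' @export
preset_design <- function(preset = c("mrna-like", "protein-like", "null"),
                          n_genes = 1000L, samples = default_design_table(),
                          seed, ...) {
  preset <- match.arg(preset)
  switch(preset,
    "mrna-like" = mrna_like_design(n_genes, samples, seed = seed, ...),
    "protein-like" = protein_like_design(n_genes, samples, seed = seed, ...),
    "null" = null_design(n_genes, samples, seed = seed, ...)
  )
}

#' Paper-scale design (approx. 4196 genes x 144 samples)
#'
#' Three growth phases x four carbon sources x 4 batches x 3 replicates.
#' Provided for full-scale timing experiments; the desk-scale default is
#' what the test suite uses.
#'
#' @return A `sample_table`.
#' @export
paper_scale_design <- function() {
  default_design_table(
    phases = growth_phases(), carbons = carbon_sources(),
    n_batches = 4L, n_replicates = 3L
  )
}

#' Simulate a count matrix with planted condition and batch structure
#'
#' @param design A [simulation_design()].
#' @return A `simulated_dataset` list: `counts` (a [count_matrix()]),
#'   `samples` (the design `sample_table`), `truth` (per-variable gene x
#'   level log2 shift matrices), and the `design`.
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  meta <- design$samples
  n_g <- design$n_genes
  n_s <- nrow(meta)
  gene_ids <- sprintf("g%04d", seq_len(n_g))
  with_seed(design$seed, {
    baseline <- stats::rnorm(n_g, design$baseline_mean, design$baseline_sd)
    log2mu <- matrix(baseline, n_g, n_s)
    truth <- list()
    for (v in names(design$effects)) {
      e <- design$effects[[v]]
      labels <- variable_labels(meta, v)
      lv <- sort(unique(labels))
      shifts <- matrix(0, n_g, length(lv), dimnames = list(gene_ids, lv))
      if (e$size != 0 && e$fraction > 0 && length(lv) > 1L) {
        affected <- sample.int(n_g, size = round(e$fraction * n_g))
        for (k in seq_along(lv)[-1L]) { # first level is the reference
          shifts[affected, k] <- e$size *
            sample(c(-1, 1), length(affected), replace = TRUE)
        }
      }
      log2mu <- log2mu + shifts[, match(labels, lv), drop = FALSE]
      truth[[v]] <- shifts
    }
    mu <- 2^log2mu
    counts <- matrix(
      stats::rnbinom(n_g * n_s, mu = mu, size = 1 / design$dispersion),
      n_g, n_s,
      dimnames = list(gene_ids, meta$sample_id)
    )
  })
  structure(
    list(
      counts = count_matrix(counts, design$omics_kind),
      samples = meta, truth = truth, design = design
    ),
    class = "simulated_dataset"
  )
}

#' Simulate an OD600 growth curve
#'
#' Exponential growth `od0 * 2^(t / true_doubling_min)` capped at `plateau`,
#' with multiplicative log-normal noise of log-scale `noise_sigma`, sampled
#' every `dt_min` minutes from 0 until well into the plateau.
#'
#' @param true_doubling_min True doubling time, minutes, > 0.
#' @param od0 Inoculation density, must be < `plateau`.
#' @param plateau Stationary-phase density.
#' @param noise_sigma Log-scale noise sd (0 = noise free).
#' @param dt_min Sampling interval, minutes.
#' @param seed Mandatory integer seed.
#' @param replicate_id,condition_id Identifiers for the curve.
#' @return A [growth_curve()].
#' @export
simulate_growth_curve <- function(true_doubling_min, od0 = 0.01, plateau = 1.0,
                                  noise_sigma = 0, dt_min = 10, seed,
                                  replicate_id = "r1", condition_id = "c1") {
  assert_scalar_number(true_doubling_min, "true_doubling_min", positive = TRUE)
  if (od0 <= 0 || od0 >= plateau) stopf("need 0 < od0 < plateau")
  if (noise_sigma < 0) stopf("`noise_sigma` must be >= 0")
  if (missing(seed)) stopf("`seed` is mandatory")
  t_plateau <- true_doubling_min * log2(plateau / od0)
  time_min <- seq(0, ceiling(t_plateau * 1.3), by = dt_min)
  od <- pmin(od0 * 2^(time_min / true_doubling_min), plateau)
  if (noise_sigma > 0) {
    od <- with_seed(seed, od * exp(stats::rnorm(length(od), 0, noise_sigma)))
  }
  growth_curve(replicate_id, condition_id, time_min, od)
}

#' Simulate a flux-ratio table with planted linear trends
#'
#' Generates 13 flux ratios for `n_conditions` conditions spanning a
#' covariate grid, with `n_replicates` replicate measurements per condition.
#' Each ratio's replicate value is `center + slope * (covariate - mean)` plus
#' Gaussian noise, clipped to `[0, 1]`. The default covariate is doubling
#' time over 50-100 minutes (the physiological range for the organism); the
#' sodium and magnesium columns span the stress grids so any covariate can
#' be regressed afterwards.
#'
#' @param n_conditions Number of conditions, default 8.
#' @param slope_per_ratio Numeric vector (recycled to 13): planted slope of
#'   each ratio vs the doubling-time covariate, in ratio units per minute.
#' @param noise_sd Replicate noise sd, default 0.05.
#' @param n_replicates Replicates per condition, default 3.
#' @param centers Per-ratio central values (recycled); default mid-range
#'   values keeping clipping rare.
#' @param seed Mandatory integer seed.
#' @param ratio_names The 13-name vocabulary.
#' @return A `flux_table` with a `doubling_time_min` column and a
#'   `truth` attribute holding the planted slopes.
#' @export
simulate_flux_table <- function(n_conditions = 8L, slope_per_ratio = 0,
                                noise_sd = 0.05, n_replicates = 3L,
                                centers = seq(0.3, 0.7, length.out = 13L),
                                seed, ratio_names = default_flux_ratio_names()) {
  if (missing(seed)) stopf("`seed` is mandatory")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (n_conditions < 3L) stopf("need >= 3 conditions for downstream regression")
  nr <- length(ratio_names)
  slopes <- rep_len(slope_per_ratio, nr)
  centers <- rep_len(centers, nr)
  dbl <- seq(50, 100, length.out = n_conditions)
  na <- seq(5, 300, length.out = n_conditions)
  mg <- exp(seq(log(0.02), log(200), length.out = n_conditions))
  rows <- expand.grid(
    replicate = seq_len(n_replicates),
    cond = seq_len(n_conditions),
    ratio = seq_len(nr)
  )
  mu <- centers[rows$ratio] + slopes[rows$ratio] * (dbl[rows$cond] - mean(dbl))
  value <- with_seed(seed, mu + stats::rnorm(nrow(rows), 0, noise_sd))
  value <- pmin(pmax(value, 0), 1)
  df <- data.frame(
    sample_id = sprintf("C%02d_R%d", rows$cond, rows$replicate),
    condition_id = sprintf("C%02d", rows$cond),
    replicate = paste0("R", rows$replicate),
    na_mM = na[rows$cond],
    mg_mM = mg[rows$cond],
    doubling_time_min = dbl[rows$cond],
    ratio_name = ratio_names[rows$ratio],
    value = value,
    stringsAsFactors = FALSE
  )
  out <- flux_table(df, ratio_names = ratio_names)
  attr(out, "truth") <- data.frame(
    ratio_name = ratio_names,
    slope = slopes, center = centers, stringsAsFactors = FALSE
  )
  out
}
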