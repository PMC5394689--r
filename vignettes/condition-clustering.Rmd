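---
title: "Quantifying condition-driven clustering in multi-omics count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying condition-driven clustering in multi-omics count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

`omicsclust` asks whether samples sharing a level of an experimental
variable — growth phase, carbon source, sodium or magnesium level, or a
technical batch — occupy a coherent region of the expression dendrogram.
The procedure is:

1. **Normalize.** Per-sample size factors by the median-of-ratios method on
   the pseudocounted matrix (`counts + 1`). The pseudocount exists because
   sparse matrices (many proteins unobserved under some condition) would
   otherwise lose every gene with a zero from the geometric-mean reference;
   with `+1` all genes contribute. The factors then divide the *raw*
   counts — the pseudocount is an estimation device, never part of the
   normalized values.
2. **Transform.** `log2(normalized + 1)`. Base and pseudocount are
   configurable; the defaults make a zero count map to exactly 0 and one
   unit equal one doubling.
3. **Cluster.** Euclidean distances between sample profiles, complete
   linkage. Complete linkage defines cluster distance as the maximum member
   distance, so merge heights are monotone non-decreasing and the cophenetic
   matrix is ultrametric by construction.
4. **Test.** For a categorical labelling, the observed statistic is the mean
   cophenetic distance over all same-label pairs (pooled across levels).
   Reshuffling the label vector uniformly at random — which preserves the
   label multiset and therefore the pair-count structure — yields a null
   sample; the z-score uses the null's mean and its n−1 standard deviation.
   `z < -1.96` is flagged as significant clustering. Per-level statistics
   restrict the pair set to one level and share the same permutations, so a
   variable's overall and level rows are mutually consistent.

The test is nonparametric: it assumes exchangeability of labels under the
null, nothing about the count distribution. What it inherits from the
pipeline is the geometry — Euclidean distance on log-normalized counts —
so heavy technical artefacts (depth, batch) must either be the variable
under test or be absent; this is why replicate QC and the batch variable
are first-class citizens.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| pseudocount (size factors) | 1 | counts | smallest value keeping zeros informative |
| pseudocount (log) | 1 | normalized counts | zero maps to 0 |
| log base | 2 | — | one unit = one doubling |
| `n_perm` | 10 000 | permutations | z estimation noise ≈ 1% of null sd |
| significance flag | z < −1.96 | — | two-sided 5% normal convention; raw z is always printed so a \|z\| > 2 convention is equally auditable |
| QC `flag_threshold` | 0.5 | log2 units | a sustained 1.4-fold median shift between replicates is past measurement noise; the report carries median, IQR and skewness so users can apply their own rule |
| Na binning | ≥ 100 mM = high | mM | reference media carry ~5 mM; stress experiments use ≥ 100 mM |
| Mg binning | < 0.8 low, = 0.8 base, > 0.8 high | mM | 0.8 mM is the reference medium concentration |
| growth window | 0.05–0.75 × max OD, inclusive | — | brackets the log-linear segment; inclusive bounds fixed because "between" is ambiguous |
| FDR procedure | Benjamini–Hochberg | — | the standard step-up rule; applied across the 13 ratios within one covariate family |

Open choices that were decided once and fixed:

* **Pooled vs averaged overall statistic.** "All same-label pairs" is read
  as one pooled, pair-weighted set; the per-level-mean alternative is
  available via `overall_method = "level_mean"`. Pooling weights a level
  with $m$ samples by $\binom{m}{2}$ pairs, which is what "all pairs"
  literally describes.
* **Global vs stratified reshuffling.** Permutations reshuffle the whole
  label vector of the variable under test. This preserves the label
  multiset exactly and is the natural exchangeability null for "does this
  labelling align with the tree".
* **Three-level growth phase.** Exponential / stationary / late-stationary
  are kept distinct by default; `default_binning(collapse_phase = TRUE)`
  gives the two-level contrast.
* **Protein rounding** is half-away-from-zero. Base R's `round()` rounds
  half to even; ties at `.5` are rare in spectral counts but the rule must
  be deterministic and documented.
* **Tie-breaking in the linkage**: among minimal-distance cluster pairs,
  the pair whose smallest contained leaf index is lowest wins, then the
  smaller second index. This makes dendrograms bit-reproducible across
  platforms regardless of float coincidences.
* **All-zero genes are retained**: after `log2(x+1)` they are identically 0
  in every sample and contribute nothing to any distance, so filtering them
  would change no result while breaking the fixed gene universe.

## What the simulator emulates — and what it does not

`simulate_counts()` draws counts from a negative binomial law
(`dispersion` 0.1 by default, variance $\mu + 0.1\mu^2$) whose log2 mean is
a per-gene baseline ($\mathcal N(6, 2^2)$, spanning the dynamic range of
real count data) plus additive per-variable shifts: a random fraction of
genes receives ±`size` log2 units in each non-reference level. The default
design is 48 samples — 2 phases × 2 carbon sources × 4 batches × 3
replicates, with ion levels varied across replicates so they stay orthogonal
to batch and condition; `paper_scale_design()` scales to 3 phases × 4
carbons (144 samples) and ~4200 genes.

Presets state the two regimes the analysis is meant to distinguish:

* `mrna_like_design()`: phase 2.0 log2 on 30% of genes, batch 0.2 on 10%,
  carbon 0.2 on 5% — transcript-like data where growth phase dominates.
* `protein_like_design()`: batch 1.0 on 30%, carbon 1.0 on 30%, phase 0.2
  on 5% — spectral-count-like data where technical batches and carbon
  source dominate and phase barely registers. The batch/carbon balance was
  calibrated (grid over effect sizes, 6 seeds each) so that *both* variables
  shape the dendrogram: with batch much stronger than carbon, complete
  linkage partitions the tree by batch and the nested carbon structure
  becomes invisible to the cophenetic statistic — an instructive failure
  mode of the statistic itself, not of the test. The calibrated preset
  reproduces the qualitative published pattern (batch z ≈ −22, carbon
  clearly significant, phase not).

The generator does **not** emulate: gene–gene correlation, library-size
gradients confounded with condition, time-course autocorrelation,
missing-not-at-random protein dropout, or count-dependent dispersion. A
green planted-signal test therefore establishes that the pipeline detects
additive log-scale structure of the stated size under NB noise — not that
it is robust to every artefact of real spectral counts.

Growth curves are `min(od0 · 2^(t/τ), plateau)` with multiplicative
log-normal noise; flux tables are linear-in-covariate ratios with Gaussian
replicate noise clipped to [0, 1]. Both are seeded and bit-reproducible.

## Numerical choices

* Size factors use the arithmetic median of per-gene ratios against the
  geometric-mean reference (not the exponentiated median of log-ratios,
  which differs for even gene counts).
* The permutation z uses the n−1 sample standard deviation of the null
  draws; with zero null spread (single-label vectors, degenerate trees) the
  result carries an `undefined` flag and a `null` z in JSON rather than an
  infinity.
* Degenerate flux regressions (zero response variance) return slope 0 with
  p = 1 by convention; zero covariate variance is an error.
* Doubling-time fits refuse windows with fewer than 3 points and
  non-positive slopes rather than reporting a negative doubling time.
* A replicate-QC pair needs ≥ 50 co-detected genes; below that the
  log-difference histogram is uninformative and the pair is skipped (or an
  error when called directly).

## Scale of the shipped experiments

The acceptance experiments run at desk scale: 1000-gene × 48-sample
datasets, 500 permutations per variable for the calibration and
planted-signal studies (chosen a priori; adds < 0.1 sd of noise to each
z-score), 100 000 permutations only for the exhaustive-null equivalence
check where precision is the point. The full suite completes in a few
minutes on one CPU. Analyses of real compendia should use the 10 000
permutation default.

## Known limitations

* Only complete linkage is implemented; the cophenetic z-score is
  linkage-dependent, and average or Ward trees would give different (not
  comparable) z values.
* The permutation null treats samples as exchangeable; nested designs
  (replicates within batches within conditions) are tested variable by
  variable, not jointly, and no multiple-testing correction is applied
  across variables — the z table is meant to be read as descriptive effect
  sizes.
* The cophenetic statistic is dominated by the tree's upper merges; a
  secondary variable nested strictly inside a much stronger one can be
  invisible (see the preset calibration note above). Testing residual
  structure after removing a known dominant effect is out of scope.
* Flux trend tests are per-ratio simple regressions; no outlier handling is
  applied, matching the source analysis, so a single extreme condition can
  drive nominal significance before FDR correction.
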