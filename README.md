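# omicsclust

Condition clustering and significance testing for multi-omics count data.

## The problem

Given genome-wide count matrices measured under many growth conditions —
bulk RNA-seq read counts and proteomics spectral counts for the same genes —
a recurring question is *which experimental variable actually drives the
global expression pattern*: growth phase? carbon source? ion stress? or a
technical batch effect? A hierarchical clustering heatmap suggests an
answer, but eyeballing a dendrogram is not a test.

`omicsclust` implements a nonparametric permutation test that turns the
dendrogram into a calibrated statistic. Samples are clustered by complete
linkage on Euclidean distances between their log-normalized expression
profiles. For a categorical design variable with labels
$\ell(1),\dots,\ell(n)$ over the $n$ samples, the observed statistic is the
mean **cophenetic distance** over same-label pairs,

$$\bar c_{\text{obs}} \;=\; \frac{1}{|P|}\sum_{(i,j)\in P} c(i,j),
\qquad P = \{(i,j): i<j,\ \ell(i)=\ell(j)\},$$

where $c(i,j)$ is the merge height at which leaves $i$ and $j$ first join.
The null distribution is generated by reshuffling the label vector uniformly
at random and recomputing $\bar c$; the report is the z-score

$$z = \frac{\bar c_{\text{obs}} - \operatorname{mean}(\bar c_{\text{null}})}
           {\operatorname{sd}(\bar c_{\text{null}})},$$

with $z < -1.96$ flagged as significant clustering (same-label samples sit
closer together in the tree than chance allows). One overall z per variable
plus one z per level are reported.

Around this core the package provides the full supporting pipeline:

* **I/O and validation** for count matrices (protein spectral counts are
  rounded half-away-from-zero; unobserved proteins become 0), sample
  metadata, OD600 growth curves and flux-ratio tables, plus versioned JSON
  result serialization.
* **Preprocessing**: replicate-consistency QC on log2 count differences,
  median-of-ratios size factors computed on `counts + 1` pseudocounts and
  applied to the raw counts, and a configurable log transform (default
  `log2(x + 1)`).
* **Clustering**: deterministic complete-linkage agglomeration (explicit
  lowest-index tie-breaking), cophenetic matrices, Newick export.
* **Growth curves**: doubling times by OLS of log OD600 on time over the
  exponential window (readings within 0.05–0.75 of the curve maximum),
  doubling time $= \ln 2 / \text{slope}$, with t-distribution confidence
  intervals across replicates.
* **Flux trend tests**: per-ratio linear regressions of replicate-averaged
  flux ratios against Na⁺ concentration, log Mg²⁺ concentration, or
  doubling time, with Benjamini–Hochberg FDR correction across the 13
  central-metabolism branch-point ratios.
* **Seeded simulators** (negative-binomial counts with planted phase /
  carbon / batch effects, growth curves, flux tables) so every stage is
  testable without any external download.

## Worked example

```r
library(omicsclust)

# 1000 genes x 48 samples with a planted growth-phase signal
sim  <- simulate_counts(mrna_like_design(n_genes = 1000, seed = 1))
sf   <- compute_size_factors(sim$counts)
logm <- log_transform(normalize_counts(sim$counts, sf))
tree <- complete_linkage(sample_distances(logm))
res  <- run_all_variables(cophenetic_matrix(tree), sim$samples,
                          n_perm = 2000, seed = 1)
subset(as.data.frame(res), level == "overall",
       select = c(variable, z, significant))
```

```
        variable           z significant
1   growth_phase -31.0325858        TRUE
4  carbon_source   0.7411811       FALSE
7       mg_level   0.9647922       FALSE
11      na_level   0.6636981       FALSE
14         batch   1.2001671       FALSE
```

The planted phase effect (2 log2 units on 30% of genes) is detected at
overwhelming significance while every unplanted variable stays within the
null band — the same qualitative contrast seen in real transcriptome
compendia, where exponential-phase samples cluster apart from stationary
ones. A protein-like preset (`protein_like_design()`) instead produces
strong batch and carbon-source clustering with phase non-significant.

The same analysis runs end-to-end from one config:

```sh
Rscript inst/cli/omicsclust run --config run.json
# run.json: {"seed": 1, "simulate_preset": "mrna-like", "out_dir": "out", "n_perm": 10000}
```

writing counts, QC, size factors, normalized and log matrices, the Newick
dendrogram, the cophenetic matrix, the z-score table and a checksummed
manifest into `out/`.

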