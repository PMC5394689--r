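# 1-D layout giving a hand-checkable dendrogram: two tight pairs far apart.
aabb_fixture <- function() {
  x <- matrix(c(0, 1, 10, 11),
    nrow = 1,
    dimnames = list("f", c("a1", "a2", "b1", "b2"))
  )
  cophenetic_matrix(complete_linkage(sample_distances(x)))
}

test_that("mean within-label distance matches hand enumeration", {
  C <- aabb_fixture()
  labels <- setNames(c("A", "A", "B", "B"), rownames(C))
  # each same-label pair sits at merge height 1; overall pools both pairs
  res <- mean_within_label_distance(C, labels, "overall")
  expect_equal(res$mean, 1)
  expect_equal(res$n_pairs, 2L)
  expect_equal(mean_within_label_distance(C, labels, "A")$mean, C["a1", "a2"])
  expect_equal(mean_within_label_distance(C, labels, "A")$n_pairs, 1L)

  # one label for everyone -> mean of the full upper triangle
  one <- setNames(rep("x", 4), rownames(C))
  ut <- unclass(C)[upper.tri(C)]
  expect_equal(mean_within_label_distance(C, one, "overall")$mean, mean(ut))

  single <- setNames(c("A", "B", "B", "B"), rownames(C))
  expect_error(mean_within_label_distance(C, single, "A"), ">= 2")
  expect_error(mean_within_label_distance(C, labels, "Z"), "not present")
})

test_that("degenerate labelings give flagged undefined results", {
  C <- aabb_fixture()
  res <- permutation_z(C, setNames(rep("only", 4), rownames(C)),
    n_perm = 100, seed = 1
  )
  expect_true(all(res$undefined))
  expect_true(all(is.na(res$z)))
  expect_error(
    permutation_z(C, setNames(c("A", "A", "B", "B"), rownames(C)),
      n_perm = 50, seed = 1
    ),
    "n_perm"
  )
})

test_that("planted 3/3 clusters attain the most negative exhaustive z", {
  # two well-separated tight triplets
  x <- matrix(c(0, 0.5, 1, 100, 100.5, 101),
    nrow = 1,
    dimnames = list("f", paste0("s", 1:6))
  )
  C <- cophenetic_matrix(complete_linkage(sample_distances(x)))
  labels <- setNames(rep(c("L", "R"), each = 3), colnames(x))

  ex <- oracle_exhaustive_null(unclass(C), labels)
  obs <- oracle_pooled_stat(unclass(C), labels)
  # the matched labeling minimizes the pooled statistic over all labelings
  expect_equal(obs, min(ex$values))

  res <- permutation_z(C, labels, n_perm = 2000, seed = 77)
  ov <- res[res$level == "overall", ]
  expect_equal(ov$observed_mean, obs)
  expect_lt(ov$z, 0)
  expect_equal(ov$null_mean, ex$mean, tolerance = 0.02)
  expect_equal(ov$null_sd, ex$sd, tolerance = 0.05)
  expect_true(ov$significant)
})

test_that("renaming levels leaves every numeric output unchanged", {
  set.seed(8)
  x <- matrix(rnorm(50), 5, 10, dimnames = list(NULL, paste0("s", 1:10)))
  C <- cophenetic_matrix(complete_linkage(sample_distances(x)))
  lab1 <- setNames(rep(c("u", "v"), 5), colnames(x))
  lab2 <- setNames(rep(c("apple", "pear"), 5), colnames(x))
  r1 <- permutation_z(C, lab1, n_perm = 300, seed = 5)
  r2 <- permutation_z(C, lab2, n_perm = 300, seed = 5)
  num <- c("observed_mean", "null_mean", "null_sd", "z", "n_pairs")
  expect_equal(r1[, num], r2[, num], ignore_attr = TRUE)
})

test_that("numeric design variables bin to the declared categorical levels", {
  meta <- sample_table(data.frame(
    sample_id = paste0("s", 1:6),
    growth_phase = c(
      "exponential", "exponential", "stationary",
      "stationary", "late_stationary", "late_stationary"
    ),
    carbon_source = "glucose",
    na_mM = c(5, 5, 99, 100, 150, 5),
    mg_mM = c(0.8, 0.08, 0.8, 8, 0.8, 0.8),
    batch = c("B1", "B1", "B1", "B2", "B2", "B2"),
    replicate = "R1"
  ))
  expect_equal(
    unname(variable_labels(meta, "na_level")),
    c("base_na", "base_na", "base_na", "high_na", "high_na", "base_na")
  )
  expect_equal(
    unname(variable_labels(meta, "mg_level")),
    c("base_mg", "low_mg", "base_mg", "high_mg", "base_mg", "base_mg")
  )
  expect_equal(
    unname(variable_labels(meta, "growth_phase", default_binning(collapse_phase = TRUE))),
    c(rep("exponential", 2), rep("stationary", 4))
  )
  expect_equal(unname(variable_labels(meta, "batch")), meta$batch)
  expect_error(variable_labels(meta, "nonexistent"), "not a metadata column")
})

test_that("run_all_variables is order-invariant and structurally complete", {
  sim <- simulate_counts(null_design(n_genes = 150, seed = 13))
  logm <- log_transform(normalize_counts(sim$counts, compute_size_factors(sim$counts)))
  C <- cophenetic_matrix(complete_linkage(sample_distances(logm)))

  res <- run_all_variables(C, sim$samples,
    variables = c("batch", "growth_phase"),
    n_perm = 200, seed = 99
  )
  # batch: 4 levels -> overall + 4 rows; phase: 2 levels -> overall + 2 rows
  expect_equal(sum(res$variable == "batch"), 5L)
  expect_equal(sum(res$variable == "growth_phase"), 3L)
  expect_true(all(c("overall") %in% res$level))

  shuffled <- sim$samples[sample(nrow(sim$samples)), , drop = FALSE]
  res2 <- run_all_variables(C, shuffled,
    variables = c("batch", "growth_phase"),
    n_perm = 200, seed = 99
  )
  expect_equal(as.data.frame(res2), as.data.frame(res))

  expect_error(
    run_all_variables(C, sim$samples[-1, ], n_perm = 200, seed = 1),
    "metadata missing"
  )
})

test_that("pooled vs per-level-mean overall statistics differ as documented", {
  C <- aabb_fixture()
  # unbalanced labels: one pair at height 1, one triple... use 4 leaves:
  labels <- setNames(c("A", "A", "A", "B"), rownames(C)) # A has 3 pairs, B none
  pooled <- permutation_z(C, labels, n_perm = 150, seed = 2)
  lm_res <- permutation_z(C, labels,
    n_perm = 150, seed = 2,
    overall_method = "level_mean"
  )
  a_pairs <- c(C["a1", "a2"], C["a1", "b1"], C["a2", "b1"])
  expect_equal(
    pooled$observed_mean[pooled$level == "overall"],
    mean(a_pairs)
  )
  # with a single contributing level the two conventions coincide here
  expect_equal(
    lm_res$observed_mean[lm_res$level == "overall"],
    mean(a_pairs)
  )
})
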