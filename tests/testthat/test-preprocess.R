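test_that("replicate QC recovers exact scalings and applies the flag rule", {
  set.seed(1)
  a <- rpois(200, 50) + 1
  qc <- check_replicate_consistency(a, a)
  expect_equal(qc$median_log2_diff, 0)
  expect_false(qc$flagged)

  qc2 <- check_replicate_consistency(2 * a, a)
  expect_equal(qc2$median_log2_diff, 1)
  expect_true(qc2$flagged) # |1| > default 0.5

  # small shift under the threshold is not flagged
  b <- round(a * 2^0.1)
  qc3 <- check_replicate_consistency(b, a, flag_threshold = 0.5)
  expect_lt(abs(qc3$median_log2_diff), 0.2)
  expect_false(qc3$flagged)

  # only co-detected genes enter: zeros on either side are ignored
  a0 <- c(a, rep(0, 50))
  b0 <- c(a, rep(1000, 50))
  qc4 <- check_replicate_consistency(a0, b0)
  expect_equal(qc4$n_codetected, 200L)
  expect_equal(qc4$median_log2_diff, 0)

  expect_error(
    check_replicate_consistency(rep(1, 30), rep(1, 30)),
    "50"
  )
})

test_that("size factors follow the pseudocounted median-of-ratios rule", {
  # two identical columns -> unit factors
  m <- matrix(c(5, 9, 2, 5, 9, 2), 3, 2,
    dimnames = list(paste0("g", 1:3), c("a", "b"))
  )
  expect_equal(compute_size_factors(m)$factor, c(1, 1))

  # (1,3,7) vs (3,7,15): pseudocounted columns are exact 2x scalings
  m2 <- matrix(c(1, 3, 7, 3, 7, 15), 3, 2,
    dimnames = list(paste0("g", 1:3), c("a", "b"))
  )
  expect_equal(compute_size_factors(m2)$factor, c(2^(-1 / 2), 2^(1 / 2)),
    tolerance = 1e-12
  )

  # an all-zero gene contributes ratio 1 everywhere and cannot move an
  # interior median
  set.seed(42)
  for (k in 1:20) {
    base <- random_counts(11, 4)
    with0 <- rbind(base, g0 = rep(0L, 4))
    f1 <- compute_size_factors(count_matrix(base, "mrna"))$factor
    f2 <- compute_size_factors(count_matrix(with0, "mrna"))$factor
    # medians over 11 vs 12 ratios: adding the 1-ratio can only pull the
    # median toward 1, never past a neighbouring order statistic
    expect_true(all(abs(f2 - f1) <= abs(f1 - 1) + 1e-12))
  }
})

test_that("size factors are scaling-equivariant and match the oracle", {
  set.seed(7)
  m <- random_counts(30, 5)
  f <- compute_size_factors(count_matrix(m, "mrna"))$factor
  # exact c-fold scaling of a pseudocounted column scales its factor by
  # exactly c relative to every other sample (the geometric-mean reference
  # absorbs a factor c^(1/S), so only relative factors are exactly scale-
  # equivariant)
  pc_scaled <- (m + 1) * ifelse(col(m) == 3, 4, 1) - 1
  f2 <- compute_size_factors(count_matrix(pc_scaled, "mrna"))$factor
  expect_equal((f2[3] / f2[-3]) / (f[3] / f[-3]), rep(4, 4), tolerance = 1e-12)

  # with many samples the absolute factor approaches c as well
  m_big <- random_counts(40, 25)
  fb <- compute_size_factors(count_matrix(m_big, "mrna"))$factor
  pc_big <- (m_big + 1) * ifelse(col(m_big) == 10, 4, 1) - 1
  fb2 <- compute_size_factors(count_matrix(pc_big, "mrna"))$factor
  expect_equal(fb2[10] / fb[10], 4, tolerance = 0.1)

  for (k in 1:10) {
    m <- random_counts(20, 6)
    expect_equal(
      compute_size_factors(count_matrix(m, "mrna"))$factor,
      oracle_size_factors(m),
      tolerance = 1e-12
    )
  }
})

test_that("normalization divides raw counts and preserves zeros", {
  m <- count_matrix(
    matrix(c(10, 0, 4, 6), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b"))),
    "mrna"
  )
  f <- data.frame(sample_id = c("a", "b"), factor = c(2, 1))
  norm <- normalize_counts(m, f)
  expect_equal(norm["g1", "a"], 5)
  expect_equal(norm["g2", "a"], 0)
  expect_equal(norm[, "b"], c(g1 = 4, g2 = 6))

  funit <- data.frame(sample_id = c("a", "b"), factor = c(1, 1))
  expect_equal(unclass(normalize_counts(m, funit)), unclass(m),
    ignore_attr = TRUE
  )
  expect_error(
    normalize_counts(m, data.frame(sample_id = "a", factor = 1)),
    "no size factor.*b"
  )
})

test_that("log transform follows the declared pseudocount rule and is monotone", {
  m <- matrix(c(0, 3, 7, 1), 2, 2)
  lt <- log_transform(m, pseudocount = 1, base = 2)
  expect_equal(lt[1, 1], 0)
  expect_equal(lt[2, 1], 2)
  expect_equal(lt[1, 2], 3)

  set.seed(3)
  x <- matrix(runif(100, 0, 50), 10, 10)
  lx <- log_transform(x)
  ord <- order(x)
  expect_true(all(diff(lx[ord]) >= 0))

  expect_error(log_transform(matrix(-1)), "nonnegative")
  expect_error(log_transform(m, pseudocount = 0), "pseudocount")
  expect_error(log_transform(m, base = 1), "base")
})
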