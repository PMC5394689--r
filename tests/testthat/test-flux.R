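test_that("bh_fdr reproduces the step-up definition", {
  # hand-computed worked example, m = 4
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")

  set.seed(12)
  for (k in 1:25) {
    p <- runif(sample(1:50, 1))
    adj <- bh_fdr(p)
    expect_identical(adj, oracle_bh(p)) # exact, including ties
    # independent library oracle; float-op order differs, so tiny tolerance
    expect_equal(adj, p.adjust(p, method = "BH"), tolerance = 1e-12)
    # monotone in the raw p-values
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= 0))
  }
})

test_that("flux regressions recover exact linear relationships", {
  ratios <- default_flux_ratio_names()
  cond <- sprintf("C%d", 1:5)
  x <- c(10, 20, 30, 40, 50)
  df <- expand.grid(condition_id = cond, ratio_name = ratios[1:2], stringsAsFactors = FALSE)
  df$sample_id <- paste0(df$condition_id, "_r1")
  df$replicate <- "R1"
  df$na_mM <- x[match(df$condition_id, cond)]
  df$mg_mM <- 0.8
  # ratio 1: exact slope 0.02 per mM; ratio 2: constant
  df$value <- ifelse(df$ratio_name == ratios[1],
    0.02 * df$na_mM - 0.1, 0.4
  )
  # lm warns about the essentially perfect fit; that is the point here
  res <- suppressWarnings(regress_flux(flux_table(df), "na_mM"))
  r1 <- res[res$ratio_name == ratios[1], ]
  r2 <- res[res$ratio_name == ratios[2], ]
  expect_equal(r1$slope, 0.02, tolerance = 1e-12)
  expect_lt(r1$p_value, 1e-10) # perfect fit
  expect_equal(r2$slope, 0) # flat response convention
  expect_equal(r2$p_value, 1)
  expect_true(all(res$p_adjusted >= res$p_value))

  # slope equals the closed form sum((x-xbar)(y-ybar)) / sum((x-xbar)^2)
  set.seed(9)
  df$value <- pmin(pmax(0.5 + 0.001 * df$na_mM + rnorm(nrow(df), 0, 0.03), 0), 1)
  res2 <- regress_flux(flux_table(df), "na_mM")
  for (rn in ratios[1:2]) {
    y <- df$value[df$ratio_name == rn][match(cond, df$condition_id[df$ratio_name == rn])]
    beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(res2$slope[res2$ratio_name == rn], beta, tolerance = 1e-12)
  }
})

test_that("replicate averaging and the magnesium log-transform are applied", {
  ratios <- default_flux_ratio_names()[1]
  df <- expand.grid(
    condition_id = sprintf("C%d", 1:4), replicate = c("R1", "R2"),
    stringsAsFactors = FALSE
  )
  df$sample_id <- paste(df$condition_id, df$replicate, sep = "_")
  df$ratio_name <- ratios
  df$na_mM <- 5
  df$mg_mM <- c(0.02, 0.2, 2, 20)[match(df$condition_id, sprintf("C%d", 1:4))]
  # value depends exactly on log(mg); replicates offset symmetrically so the
  # replicate mean reproduces the exact line
  base_val <- 0.3 + 0.05 * log(df$mg_mM)
  df$value <- base_val + ifelse(df$replicate == "R1", 0.01, -0.01)
  res <- suppressWarnings(regress_flux(flux_table(df), "log_mg_mM"))
  expect_equal(res$slope, 0.05, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-8)

  # doubling-time covariate requires the column
  expect_error(regress_flux(flux_table(df), "doubling_time_min"), "doubling_time_min")

  # fewer than 3 distinct covariate values is an error
  df2 <- df[df$condition_id %in% c("C1", "C2"), ]
  expect_error(regress_flux(flux_table(df2), "log_mg_mM"), ">= 3")
})

test_that("simulated flux tables are deterministic and bounded", {
  f1 <- simulate_flux_table(n_conditions = 6, slope_per_ratio = 0.002, seed = 42)
  f2 <- simulate_flux_table(n_conditions = 6, slope_per_ratio = 0.002, seed = 42)
  expect_identical(f1, f2)
  f3 <- simulate_flux_table(n_conditions = 6, slope_per_ratio = 0.002, seed = 43)
  expect_false(identical(f1$value, f3$value))
  expect_true(all(f1$value >= 0 & f1$value <= 1))
  expect_equal(length(unique(f1$ratio_name)), 13L)
  expect_equal(nrow(f1), 6 * 3 * 13)
})
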