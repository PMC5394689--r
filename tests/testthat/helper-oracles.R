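# Independent brute-force oracles. These deliberately re-derive results from
# first principles (rescanning definitions, explicit loops) so they share no
# code path with the implementation they check.

# Complete-linkage agglomeration by rescanning the full pairwise table at
# every step, reading cluster distances as maxima over member pairs of the
# ORIGINAL distance matrix. Returns the cophenetic matrix by direct
# merge-height lookup. Tie-break mirrors the declared contract: the pair
# whose smallest contained leaf index is lowest, then the second index.
oracle_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  C <- matrix(0, n, n, dimnames = dimnames(D))
  while (length(clusters) > 1L) {
    best <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        h <- max(D[clusters[[a]], clusters[[b]]])
        key <- c(
          h,
          min(min(clusters[[a]]), min(clusters[[b]])),
          max(min(clusters[[a]]), min(clusters[[b]]))
        )
        if (is.null(best) || key[1] < best$key[1] - 1e-15 ||
          (abs(key[1] - best$key[1]) <= 1e-15 &&
            (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(a = a, b = b, key = key)
        }
      }
    }
    h <- best$key[1]
    C[clusters[[best$a]], clusters[[best$b]]] <- h
    C[clusters[[best$b]], clusters[[best$a]]] <- h
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  C
}

# Median-of-ratios size factors, re-derived with explicit per-gene loops.
oracle_size_factors <- function(m) {
  pc <- m + 1
  n_genes <- nrow(pc)
  ref <- numeric(n_genes)
  for (g in seq_len(n_genes)) ref[g] <- prod(pc[g, ])^(1 / ncol(pc))
  out <- numeric(ncol(pc))
  for (s in seq_len(ncol(pc))) {
    ratios <- numeric(n_genes)
    for (g in seq_len(n_genes)) ratios[g] <- pc[g, s] / ref[g]
    out[s] <- median(ratios)
  }
  out
}

# BH step-up straight from the definition: adj_i = min_{j: p_j-rank >= rank_i}
# p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# All permutations of 1..n (n small), one row each.
all_perms <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

# Pooled same-label mean cophenetic distance, plain loops.
oracle_pooled_stat <- function(C, labels) {
  tot <- 0
  np <- 0L
  n <- nrow(C)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (labels[i] == labels[j]) {
        tot <- tot + C[i, j]
        np <- np + 1L
      }
    }
  }
  tot / np
}

# Exhaustive permutation null (mean, population sd) of the pooled statistic.
oracle_exhaustive_null <- function(C, labels) {
  P <- all_perms(length(labels))
  vals <- apply(P, 1L, function(idx) oracle_pooled_stat(C, labels[idx]))
  list(mean = mean(vals), sd = sqrt(mean((vals - mean(vals))^2)), values = vals)
}

# Random integer count matrix fixture.
random_counts <- function(n_genes, n_samples, max_count = 200) {
  m <- matrix(
    sample.int(max_count + 1L, n_genes * n_samples, replace = TRUE) - 1L,
    n_genes, n_samples,
    dimnames = list(
      paste0("g", seq_len(n_genes)),
      paste0("s", seq_len(n_samples))
    )
  )
  m
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
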