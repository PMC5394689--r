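test_that("Euclidean sample distances match hand geometry", {
  x <- matrix(c(0, 0, 3, 4), nrow = 2, dimnames = list(
    c("f1", "f2"), c("a", "b")
  ))
  d <- sample_distances(x)
  expect_equal(d["a", "b"], 5) # 3-4-5 triangle
  expect_equal(diag(unclass(d)), c(a = 0, b = 0))

  set.seed(2)
  m <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("s", 1:6)))
  d1 <- sample_distances(m)
  d2 <- sample_distances(m[sample(10), , drop = FALSE]) # permute features
  expect_equal(unclass(d1), unclass(d2), tolerance = 1e-12)

  m[3, 2] <- NA
  expect_error(sample_distances(m), "non-finite.*s2")
})

test_that("complete linkage reproduces the hand-built 1-D example", {
  x <- matrix(c(0, 1, 10), nrow = 1, dimnames = list("f", c("p0", "p1", "p10")))
  tree <- complete_linkage(sample_distances(x))
  expect_equal(tree$height, c(1, 10)) # {0,1} at 1, then max(10, 9) = 10
  C <- cophenetic_matrix(tree)
  expect_equal(C["p0", "p1"], 1)
  expect_equal(C["p0", "p10"], 10)
  expect_equal(C["p1", "p10"], 10)

  # all identical points -> all merge heights zero
  xx <- matrix(1, 3, 4, dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(complete_linkage(sample_distances(xx))$height, rep(0, 3))

  expect_error(
    complete_linkage(distance_matrix(matrix(0, 1, 1, dimnames = list("a", "a")))),
    "at least 2"
  )
})

test_that("linkage heights never decrease and cophenetic output is ultrametric", {
  set.seed(11)
  for (k in 1:25) {
    n <- sample(3:12, 1)
    x <- matrix(rnorm(5 * n), 5, n, dimnames = list(NULL, paste0("s", 1:n)))
    tree <- complete_linkage(sample_distances(x))
    expect_true(all(diff(tree$height) >= -1e-12))
    expect_true(is_ultrametric(cophenetic_matrix(tree)))
  }
})

test_that("clustering an ultrametric matrix returns it exactly", {
  set.seed(5)
  for (k in 1:10) {
    n <- sample(4:9, 1)
    x <- matrix(rnorm(4 * n), 4, n, dimnames = list(NULL, paste0("s", 1:n)))
    U <- cophenetic_matrix(complete_linkage(sample_distances(x)))
    U2 <- cophenetic_matrix(complete_linkage(distance_matrix(unclass(U))))
    expect_equal(unclass(U2), unclass(U), tolerance = 1e-12)
  }
})

test_that("implementation agrees with stats::hclust on tie-free data", {
  set.seed(21)
  for (k in 1:10) {
    n <- sample(5:20, 1)
    x <- matrix(rnorm(8 * n), 8, n, dimnames = list(NULL, paste0("s", 1:n)))
    d <- stats::dist(t(x))
    hc <- stats::hclust(d, method = "complete")
    mine <- complete_linkage(sample_distances(x))
    expect_equal(mine$height, hc$height, tolerance = 1e-9)
    expect_equal(
      unclass(cophenetic_matrix(mine)),
      as.matrix(stats::cophenetic(hc))[mine$labels, mine$labels],
      tolerance = 1e-9
    )
  }
})

test_that("newick export preserves cophenetic distances", {
  skip_if_not_installed("ape")
  set.seed(31)
  x <- matrix(rnorm(40), 5, 8, dimnames = list(NULL, paste0("s", 1:8)))
  tree <- complete_linkage(sample_distances(x))
  path <- tempfile(fileext = ".nwk")
  to_newick(tree, path)
  phy <- ape::read.tree(path)
  D <- ape::cophenetic.phylo(phy) # path lengths: 2 x merge height
  C <- cophenetic_matrix(tree)
  expect_equal(D[rownames(C), colnames(C)], 2 * unclass(C), tolerance = 1e-6)
})

test_that("as.hclust conversion yields a valid hclust object", {
  set.seed(41)
  x <- matrix(rnorm(30), 5, 6, dimnames = list(NULL, paste0("s", 1:6)))
  hc <- as.hclust(complete_linkage(sample_distances(x)))
  expect_s3_class(hc, "hclust")
  expect_setequal(hc$order, 1:6)
  expect_equal(sort(unique(as.vector(stats::cutree(hc, k = 2)))), c(1, 2))
})
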