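# Normalization, linked-matrix extraction and meta-cell construction.

test_that("normalization schemes behave at their fixed points", {
  ds <- toy_dataset(n = 5, p = 3)
  expect_equal(normalize_modality(ds, "none")$matrix, ds$matrix)

  # constant feature under z-score becomes all zeros, never NaN
  m <- cbind(rep(2, 4), rnorm(4))
  dsc <- modality_dataset(m, feature_ids = c("const", "var"))
  z <- normalize_modality(dsc, "zscore_per_feature")$matrix
  expect_equal(unname(z[, 1]), rep(0, 4))
  expect_false(anyNA(z))

  # population-SD z-score, hand-computed
  ds2 <- modality_dataset(rbind(c(1, 3), c(3, 1)),
    feature_ids = c("a", "b"))
  expect_equal(
    unname(normalize_modality(ds2, "zscore_per_feature")$matrix),
    rbind(c(-1, 1), c(1, -1))
  )

  expect_error(normalize_modality(ds, "quantile"), "unknown normalization")
})

test_that("linked matrices share column order on both sides", {
  d1 <- toy_dataset(n = 3, p = 4, prefix = "g")
  d2 <- toy_dataset(n = 5, p = 4, prefix = "p", seed = 2)
  lk <- linkage_map(c("g2", "g4"), c("p1", "p3"))
  lm <- make_linked_matrices(d1, d2, lk)
  expect_equal(dim(lm$linked_1), c(3L, 2L))
  expect_equal(dim(lm$linked_2), c(5L, 2L))
  expect_equal(colnames(lm$linked_1), colnames(lm$linked_2))
  expect_equal(unname(lm$linked_1[, 1]), unname(d1$matrix[, 2]))
  expect_equal(unname(lm$linked_2[, 2]), unname(d2$matrix[, 3]))

  # permuting the link rows permutes the columns identically on both sides
  lk_perm <- linkage_map(c("g4", "g2"), c("p3", "p1"))
  lm2 <- make_linked_matrices(d1, d2, lk_perm)
  expect_equal(lm2$linked_1, lm$linked_1[, c(2, 1)])
  expect_equal(lm2$linked_2, lm$linked_2[, c(2, 1)])
})

test_that("target size 1 gives the identity meta-cell map", {
  ds <- toy_dataset(n = 8, p = 3)
  map <- build_metacells(ds, target_size = 1)
  expect_equal(map$assignment, 1:8)
  expect_equal(map$all_means, ds$matrix)
})

test_that("bisection lands the meta-cell count in the target band", {
  set.seed(4)
  m <- matrix(rnorm(100 * 10), 100, 10)
  ds <- modality_dataset(m)
  map <- build_metacells(ds, target_size = 2, k_nn = 10, seed = 11)
  expect_gte(map$n_meta, 40)
  expect_lte(map$n_meta, 67)
  expect_equal(sum(map$sizes), 100)
})

test_that("well-separated blobs aggregate to pure meta-cells", {
  bp <- blob_pair(n_per = 10, sep = 30, seed = 5)
  ds <- modality_dataset(bp$matrix)
  map <- build_metacells(ds, target_size = 10, k_nn = 5, seed = 2)
  expect_equal(map$n_meta, 2L)
  purity <- vapply(
    split(bp$labels, map$assignment),
    function(x) mean(x == x[1]), numeric(1)
  )
  expect_equal(unname(purity), c(1, 1))
})

test_that("meta-cell means preserve the weighted grand mean", {
  set.seed(6)
  ds <- modality_dataset(matrix(rnorm(60 * 5), 60, 5))
  lk <- matrix(rnorm(60 * 3), 60, 3)
  map <- build_metacells(ds, lk, target_size = 3, k_nn = 8, seed = 3)
  grand_all <- colSums(map$all_means * map$sizes) / sum(map$sizes)
  expect_equal(grand_all, colMeans(ds$matrix),
    tolerance = 1e-10, ignore_attr = TRUE)
  grand_lk <- colSums(map$linked_means * map$sizes) / sum(map$sizes)
  expect_equal(grand_lk, colMeans(lk), tolerance = 1e-10,
    ignore_attr = TRUE)
  # every meta-cell mean is the arithmetic mean of its members
  for (g in seq_len(map$n_meta)) {
    rows <- which(map$assignment == g)
    expect_equal(map$all_means[g, ],
      colMeans(ds$matrix[rows, , drop = FALSE]),
      tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("meta-cell construction is deterministic under a fixed seed", {
  set.seed(8)
  ds <- modality_dataset(matrix(rnorm(80 * 6), 80, 6))
  a <- build_metacells(ds, target_size = 2, k_nn = 8, seed = 21)
  b <- build_metacells(ds, target_size = 2, k_nn = 8, seed = 21)
  expect_identical(a$assignment, b$assignment)
})

test_that("infeasible neighborhood sizes are rejected", {
  ds <- toy_dataset(n = 5, p = 3)
  expect_error(build_metacells(ds, target_size = 2, k_nn = 5), "k_nn")
})
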