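# The synthetic co-assay generator: determinism, ground-truth bookkeeping,
# and linkage-strength calibration.

test_that("identical seeds reproduce the dataset exactly", {
  a <- simulate_modalities(n_cells = 100, seed = 5)
  b <- simulate_modalities(n_cells = 100, seed = 5)
  expect_identical(a$mod1$matrix, b$mod1$matrix)
  expect_identical(a$mod2$matrix, b$mod2$matrix)
  expect_identical(a$truth$pairing, b$truth$pairing)
})

test_that("the truth pairing is a bijection between retained cells", {
  sim <- simulate_modalities(n_cells = 150, seed = 2)
  tp <- sim$truth$pairing
  expect_equal(nrow(tp), 150L)
  expect_setequal(tp$idx_1, 1:150)
  expect_setequal(tp$idx_2, 1:150)
  # paired rows carry the same cluster label
  expect_true(all(
    sim$truth$clusters[[1]][tp$idx_1] == sim$truth$clusters[[2]][tp$idx_2]
  ))
})

test_that("realized linked-feature correlation tracks rho", {
  for (seed in 1:5) {
    sim <- simulate_modalities(
      n_cells = 2000, n_clusters = 5, s_linked = 20, rho = 0.6,
      seed = seed
    )
    lm <- make_linked_matrices(sim$mod1, sim$mod2, sim$linkage_12)
    tp <- sim$truth$pairing
    cors <- vapply(seq_len(20), function(j) {
      cor(lm$linked_1[tp$idx_1, j], lm$linked_2[tp$idx_2, j])
    }, numeric(1))
    expect_lt(abs(mean(cors) - 0.6), 0.1)
  }
})

test_that("rho zero leaves linked features uncorrelated", {
  sim <- simulate_modalities(
    n_cells = 2000, s_linked = 20, rho = 0, seed = 3
  )
  lm <- make_linked_matrices(sim$mod1, sim$mod2, sim$linkage_12)
  tp <- sim$truth$pairing
  cors <- vapply(seq_len(20), function(j) {
    cor(lm$linked_1[tp$idx_1, j], lm$linked_2[tp$idx_2, j])
  }, numeric(1))
  expect_lt(mean(abs(cors)), 0.05)
})

test_that("the noiseless strong-linkage limit is affinely self-matching", {
  sim <- simulate_modalities(
    n_cells = 120, n_clusters = 3, p1 = 40, p2 = 20, s_linked = 12,
    rho = 1, noise_sd_1 = 0, noise_sd_2 = 0, seed = 4
  )
  lm <- make_linked_matrices(sim$mod1, sim$mod2, sim$linkage_12)
  tp <- sim$truth$pairing
  # each linked column pair is affinely identical at the true pairing
  for (j in c(1, 7, 12)) {
    expect_gt(cor(lm$linked_1[tp$idx_1, j], lm$linked_2[tp$idx_2, j]),
      1 - 1e-10)
  }
  # initial matching alone recovers the truth
  z1 <- maxfuse:::zscore_cols(lm$linked_1)
  z2 <- maxfuse:::zscore_cols(lm$linked_2)
  m <- initial_match(z1, z2)
  key <- paste(tp$idx_1, tp$idx_2)
  expect_equal(mean(paste(m$idx_1, m$idx_2) %in% key), 1)
})

test_that("removing a cluster yields a partial, label-consistent pairing", {
  sim <- simulate_modalities(
    n_cells = 120, n_clusters = 4, seed = 6,
    missing_cluster = list(modality = 2, cluster = 3)
  )
  tp <- sim$truth$pairing
  expect_lt(nrow(tp), 120L)
  expect_false("cluster_3" %in% sim$truth$clusters[[2]])
  expect_true("cluster_3" %in% sim$truth$clusters[[1]])
  expect_error(
    simulate_modalities(n_cells = 50, n_clusters = 2,
      missing_cluster = list(modality = 1, cluster = 1)),
    "fewer than 2"
  )
})

test_that("panel reduction keeps the top-ranked linked features", {
  sim <- simulate_modalities(n_cells = 80, p2 = 30, s_linked = 10, seed = 7)
  red_full <- reduce_panel(sim$mod2, sim$linkage_12, keep_k = 10)
  expect_equal(nrow(red_full$linkage), 10L)
  expect_equal(dim(red_full$dataset$matrix), dim(sim$mod2$matrix))

  red1 <- reduce_panel(sim$mod2, sim$linkage_12, keep_k = 1)
  expect_equal(nrow(red1$linkage), 1L)
  expect_equal(ncol(red1$dataset$matrix), 30L - 9L)
  # the survivor is the highest-variance linked feature
  lm <- make_linked_matrices(sim$mod1, sim$mod2, sim$linkage_12)
  best <- colnames(lm$linked_2)[which.max(apply(lm$linked_2, 2, var))]
  expect_equal(paste(red1$linkage$feature_1, red1$linkage$feature_2,
    sep = "|"), best)

  expect_error(reduce_panel(sim$mod2, sim$linkage_12, keep_k = 11),
    "exceeds")
})

test_that("more linked features never hurt on easy data", {
  sim <- simulate_modalities(
    n_cells = 300, n_clusters = 4, p1 = 80, p2 = 30, s_linked = 20,
    rho = 0.95, noise_sd_1 = 0.3, noise_sd_2 = 0.3, seed = 8
  )
  cfg <- maxfuse_config(
    metacell_size1 = 1, metacell_size2 = 1, n_iter = 1,
    k_nn1 = 10, k_nn2 = 10
  )
  acc_for <- function(keep_k) {
    red <- reduce_panel(sim$mod2, sim$linkage_12, keep_k = keep_k)
    fit <- maxfuse_fit(sim$mod1, red$dataset, red$linkage, cfg)
    matching_accuracy(
      fit$matching, sim$truth$clusters[[1]], sim$truth$clusters[[2]]
    )
  }
  expect_gte(acc_for(20), acc_for(5))
})
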