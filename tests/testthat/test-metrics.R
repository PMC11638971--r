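# Evaluation criteria: accuracy, NN matching, FOSCTTM/FOSKNN, F1 scores.

test_that("matching accuracy counts label agreement", {
  mt <- maxfuse:::new_match_table(1:4, 1:4, distance = 0)
  expect_equal(matching_accuracy(mt, rep("a", 4), rep("a", 4)), 1)
  expect_equal(
    matching_accuracy(mt, c("a", "a", "b", "b"), c("a", "b", "a", "b")), 0.5
  )
  expect_error(matching_accuracy(mt[0, ], "a", "a"), "empty")
  expect_error(
    matching_accuracy(mt, c("a", NA, "a", "a"), rep("a", 4)),
    "index 2"
  )
})

test_that("embedding NN matching is exact, minimal and scale-invariant", {
  set.seed(1)
  e <- matrix(rnorm(12), 4, 3)
  m <- knn_match_from_embedding(e, e)
  expect_equal(m$idx_2, 1:4)

  # one query, three references
  q <- matrix(c(1, 2, 3), 1, 3)
  refs <- rbind(c(3, 2, 1), c(2, 4, 6), c(0, 0, 1))
  m1 <- knn_match_from_embedding(q, refs)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$idx_2, 2L)

  # positive row scaling of the references changes nothing
  sc <- diag(c(7, 0.1, 3))
  m2 <- knn_match_from_embedding(e, sc %*% e[1:3, ] * 2, "2_to_1")
  m3 <- knn_match_from_embedding(e, e[1:3, ], "2_to_1")
  expect_equal(m2$idx_1, m3$idx_1)
})

test_that("FOSCTTM and FOSKNN hit their closed-form cases", {
  set.seed(2)
  e <- matrix(rnorm(20), 10, 2)
  expect_equal(foscttm(e, e), 0)
  expect_equal(fosknn(e, e, k = 1), 1)
  expect_equal(fosknn(e, e, k = 10), 1)

  # two cells with swapped embeddings
  e1 <- matrix(c(0, 1, 0, 1), 2, 2)
  e2 <- e1[2:1, ]
  expect_equal(foscttm(e1, e2), 0.5)
  expect_equal(fosknn(e1, e2, k = 1), 0)
  expect_equal(fosknn(e1, e2, k = 2), 1)

  expect_error(foscttm(e, e[1:5, ]), "equal row counts")
})

test_that("independent embeddings give FOSCTTM near one half", {
  set.seed(3)
  a <- matrix(rnorm(500 * 3), 500, 3)
  b <- matrix(rnorm(500 * 3), 500, 3)
  expect_lt(abs(foscttm(a, b) - 0.5), 0.05)
})

test_that("FOSCTTM equals the double-loop counting oracle", {
  set.seed(4)
  for (rep in 1:5) {
    N <- sample(5:30, 1)
    e1 <- matrix(rnorm(N * 3), N, 3)
    e2 <- e1 + 0.5 * matrix(rnorm(N * 3), N, 3)
    expect_equal(foscttm(e1, e2), foscttm_oracle(e1, e2))
  }
})

test_that("rigid motions of the joint space leave FOSCTTM/FOSKNN unchanged", {
  set.seed(5)
  e1 <- matrix(rnorm(40 * 3), 40, 3)
  e2 <- e1 + 0.3 * matrix(rnorm(40 * 3), 40, 3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  shift <- matrix(rnorm(3), 40, 3, byrow = TRUE)
  r1 <- e1 %*% Q + shift
  r2 <- e2 %*% Q + shift
  expect_equal(foscttm(e1, e2), foscttm(r1, r2), tolerance = 1e-12)
  ks <- c(1, 3, 5, 10)
  expect_equal(fosknn(e1, e2, ks), fosknn(r1, r2, ks), tolerance = 1e-12)
  # nondecreasing in k
  expect_true(all(diff(fosknn(e1, e2, ks)) >= 0))
})

test_that("silhouette F1 is the harmonic mean of mixing and clustering", {
  set.seed(6)
  # two separated cell types, modalities perfectly interleaved
  ct <- rep(c("A", "B"), each = 40)
  emb <- rbind(
    matrix(rnorm(40 * 2), 40, 2),
    matrix(rnorm(40 * 2, mean = 8), 40, 2)
  )
  modality <- rep(c("m1", "m2"), 40)
  res <- silhouette_f1(emb, modality, ct)
  expect_equal(res$f1,
    2 * res$slt_mix * res$slt_clust / (res$slt_mix + res$slt_clust))
  expect_gt(res$slt_clust, 0.8) # types well separated
  expect_gt(res$slt_mix, 0.4)   # modalities mixed

  # modality-separated embedding scores poorly on mixing
  bad <- silhouette_f1(emb, ct, ct)
  expect_lt(bad$slt_mix, 0.1)
  expect_lt(bad$f1, res$f1)

  expect_error(silhouette_f1(emb, modality, rep("A", 80)), "single label")
})

test_that("ARI F1 rewards biology-aligned, modality-blind clusters", {
  set.seed(7)
  ct <- rep(c("A", "B", "C"), each = 60)
  emb <- rbind(
    matrix(rnorm(60 * 2, 0), 60, 2),
    matrix(rnorm(60 * 2, 10), 60, 2),
    matrix(rnorm(60 * 2, 20), 60, 2)
  )
  modality <- rep(rep(c("m1", "m2"), each = 30), 3)
  good <- ari_f1(emb, modality, ct, seed = 1)
  expect_gt(good$ari_clust, 0.95)
  expect_gt(good$ari_mix, 0.95)

  # clusters tracking modality exactly give F1 zero
  bad <- ari_f1(emb[1:120, ], ct[1:120], ct[1:120],
    n_clusters = 2, seed = 1)
  expect_equal(bad$f1, 0)
})

test_that("the bundled report carries every criterion", {
  set.seed(8)
  sim <- simulate_modalities(
    n_cells = 120, n_clusters = 3, p1 = 40, p2 = 20, s_linked = 10,
    rho = 0.9, seed = 9
  )
  cfg <- maxfuse_config(
    metacell_size1 = 1, metacell_size2 = 1, n_iter = 1,
    k_nn1 = 8, k_nn2 = 8, r_e = 6
  )
  fit <- maxfuse_fit(sim$mod1, sim$mod2, sim$linkage_12, cfg)
  rep_ <- evaluate_integration(
    fit$matching, fit$embeddings[[1]], fit$embeddings[[2]],
    sim$truth$clusters[[1]], sim$truth$clusters[[2]],
    truth_pairing = sim$truth$pairing, k = c(1, 5)
  )
  expect_true(all(c(
    "accuracy", "slt_f1", "ari_f1", "foscttm", "fosknn_k1", "fosknn_k5"
  ) %in% names(rep_)))
  expect_gte(rep_$fosknn_k5, rep_$fosknn_k1)
})
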