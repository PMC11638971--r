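# SVD projection/denoising, cross-modal distances, linear assignment.

test_that("svd projection reconstructs, preserves geometry, and is signed
           deterministically", {
  set.seed(1)
  A <- matrix(rnorm(8 * 3), 8, 3)
  # full rank: denoised reconstruction equals the input
  expect_equal(svd_denoise(A, 3), A, tolerance = 1e-10)

  # rank-1 input: one component reproduces pairwise distances exactly
  u <- rnorm(6)
  v <- rnorm(4)
  R1 <- outer(u, v)
  s1 <- svd_project(R1, 1)
  expect_equal(
    as.matrix(dist(s1)), as.matrix(dist(scale(R1, scale = FALSE))),
    tolerance = 1e-10, ignore_attr = TRUE
  )

  # orthogonal rotation of columns leaves score distances unchanged
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(
    as.matrix(dist(svd_project(A, 2))),
    as.matrix(dist(svd_project(A %*% Q, 2))),
    tolerance = 1e-10
  )

  # deterministic sign: recomputation is identical, not just up to sign
  expect_identical(svd_project(A, 2), svd_project(A, 2))
  expect_error(svd_project(A, 4), "exceeds")
})

test_that("cross distances match hand-computed Pearson values", {
  A <- matrix(c(1, 2), 1, 2)
  B <- rbind(c(2, 4), c(2, 1))
  D <- cross_distance(A, B, metric = "correlation")
  expect_equal(as.numeric(D), c(0, 2))

  # identical and anticorrelated rows hit the range endpoints
  X <- rbind(c(0, 1, 2), c(2, 1, 0))
  D2 <- cross_distance(X, X, metric = "correlation")
  expect_equal(diag(D2), c(0, 0))
  expect_equal(D2[1, 2], 2)

  # euclidean agrees with stats::dist
  set.seed(2)
  M <- matrix(rnorm(15), 5, 3)
  expect_equal(
    cross_distance(M, M, metric = "euclidean"),
    as.matrix(dist(M)),
    tolerance = 1e-10, ignore_attr = TRUE
  )

  expect_error(cross_distance(matrix(1, 2, 1), matrix(1, 2, 1),
    metric = "correlation"), "at least 2 columns")
  expect_error(cross_distance(matrix(1, 2, 2), matrix(1, 2, 3)),
    "column mismatch")
})

test_that("assignment solves the stated examples", {
  m <- linear_assignment(rbind(c(0, 1), c(1, 0)))
  expect_equal(m$idx_2, c(1L, 2L))
  expect_equal(attr(m, "objective"), 0)

  m1 <- linear_assignment(matrix(5, 1, 1))
  expect_equal(nrow(m1), 1L)
  expect_equal(attr(m1, "objective"), 5)

  m2 <- linear_assignment(rbind(c(1, 2, 3), c(2, 4, 1)))
  expect_equal(m2$idx_2, c(1L, 3L))
  expect_equal(attr(m2, "objective"), 2)

  expect_error(linear_assignment(matrix(numeric(0), 0, 0)), "empty")
  expect_error(linear_assignment(matrix(c(1, Inf), 1, 2)), "finite")
})

test_that("assignment matches brute-force enumeration on random instances", {
  set.seed(42)
  for (rep in 1:100) {
    nr <- sample(1:6, 1)
    nc <- sample(1:6, 1)
    D <- matrix(runif(nr * nc), nr, nc)
    m <- linear_assignment(D)
    expect_equal(nrow(m), min(nr, nc))
    expect_equal(attr(m, "objective"), brute_force_lap(D),
      tolerance = 1e-12)
  }
})

test_that("adding a constant shifts the objective but not the pairs", {
  set.seed(7)
  D <- matrix(runif(20), 4, 5)
  a <- linear_assignment(D)
  b <- linear_assignment(D + 3)
  expect_match_equal(a, b)
  expect_equal(attr(b, "objective"), attr(a, "objective") + 4 * 3,
    tolerance = 1e-10)
})

test_that("initial matching recovers a row permutation exactly", {
  set.seed(5)
  Y <- matrix(rnorm(20 * 6), 20, 6)
  perm <- sample(20)
  Z <- Y[perm, ]
  m <- initial_match(Y, Z, svd1 = 6, svd2 = 6)
  expect_equal(nrow(m), 20L)
  expect_equal(m$idx_2[order(m$idx_1)], order(perm))
  expect_equal(attr(m, "objective"), 0, tolerance = 1e-8)
})

test_that("initial pairs join same-cluster cells across separated blobs", {
  b1 <- blob_pair(n_per = 5, p = 6, sep = 15, seed = 3)
  b2 <- blob_pair(n_per = 5, p = 6, sep = 15, seed = 4)
  m <- initial_match(b1$matrix, b2$matrix)
  expect_true(all(b1$labels[m$idx_1] == b2$labels[m$idx_2]))
})

test_that("pair count always equals the smaller side", {
  set.seed(6)
  m <- initial_match(matrix(rnorm(5 * 4), 5, 4), matrix(rnorm(8 * 4), 8, 4))
  expect_equal(nrow(m), 5L)
})

test_that("batched matching reduces to unbatched for one batch and is
           seeded-deterministic", {
  set.seed(8)
  A <- matrix(rnorm(30 * 4), 30, 4)
  B <- matrix(rnorm(12 * 4), 12, 4)
  full <- batched_match(A, B, batch_size = Inf)
  one <- batched_match(A, B, batch_size = 100)
  expect_match_equal(full, one)

  b1 <- batched_match(A, B, batch_size = 10, seed = 3)
  b2 <- batched_match(A, B, batch_size = 10, seed = 3)
  expect_identical(b1, b2)

  # every cell of the larger (batched) side is covered
  expect_setequal(b1$idx_1, 1:30)
})
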