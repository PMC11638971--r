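# PCA reduction, canonical correlation and generalized CCA.

test_that("PCA scores preserve geometry where the subspace is exact", {
  # colinear points in 3-D: one component keeps all inter-point distances
  t_ <- seq(0, 1, length.out = 7)
  line <- cbind(2 * t_, -t_, 3 * t_)
  s <- pca_reduce(line, 1)
  expect_equal(
    as.matrix(dist(s)), as.matrix(dist(line)),
    tolerance = 1e-10, ignore_attr = TRUE
  )

  # r = p with n > p: isometry
  set.seed(1)
  X <- matrix(rnorm(20 * 4), 20, 4)
  expect_equal(
    as.matrix(dist(pca_reduce(X, 4))), as.matrix(dist(X)),
    tolerance = 1e-10, ignore_attr = TRUE
  )

  # duplicated rows give duplicated score rows
  Xd <- rbind(X, X[3, ])
  sd_ <- pca_reduce(Xd, 2)
  expect_equal(sd_[21, ], sd_[3, ], tolerance = 1e-10)

  expect_error(pca_reduce(X, 5), "exceeds")
})

test_that("CCA attains correlation one on identical or rotated inputs", {
  set.seed(2)
  X <- matrix(rnorm(50 * 4), 50, 4)
  fit <- cca_fit(X, X, r_cc = 4, ridge = 0)
  expect_equal(fit$correlations, rep(1, 4), tolerance = 1e-8)

  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  fit_q <- cca_fit(X, X %*% Q, r_cc = 4, ridge = 0)
  expect_equal(fit_q$correlations, rep(1, 4), tolerance = 1e-8)
})

test_that("independent high-n sides show near-zero leading correlation", {
  set.seed(3)
  X <- matrix(rnorm(2000 * 2), 2000, 2)
  Z <- matrix(rnorm(2000 * 2), 2000, 2)
  fit <- cca_fit(X, Z, r_cc = 2, ridge = 0)
  expect_lt(fit$correlations[1], 0.1)
})

test_that("canonical correlations match the generalized-eigenvalue oracle", {
  set.seed(4)
  for (rep in 1:50) {
    p <- sample(2:10, 1)
    q <- sample(2:10, 1)
    n <- 200
    X <- matrix(rnorm(n * p), n, p)
    Z <- 0.5 * X[, rep_len(seq_len(p), q)] + matrix(rnorm(n * q), n, q)
    r <- min(p, q)
    fit <- cca_fit(X, Z, r_cc = r, ridge = 0)
    oracle <- sort(cca_oracle(X, Z), decreasing = TRUE)[seq_len(r)]
    expect_equal(fit$correlations, oracle, tolerance = 1e-8)
  }
})

test_that("correlations are invariant to simultaneous row permutation", {
  set.seed(5)
  X <- matrix(rnorm(40 * 3), 40, 3)
  Z <- matrix(rnorm(40 * 3), 40, 3)
  perm <- sample(40)
  a <- cca_fit(X, Z, r_cc = 3, ridge = 0)
  b <- cca_fit(X[perm, ], Z[perm, ], r_cc = 3, ridge = 0)
  expect_equal(a$correlations, b$correlations, tolerance = 1e-10)
})

test_that("degenerate covariance at ridge zero advises regularization", {
  X <- cbind(1:10, 1:10) # rank 1
  Z <- matrix(rnorm(20), 10, 2)
  expect_error(cca_fit(X, Z, r_cc = 2, ridge = 0), "ridge")
})

test_that("cc scores are consistent between pivot-only and full matrices", {
  set.seed(6)
  X <- matrix(rnorm(30 * 4), 30, 4)
  Z <- matrix(rnorm(30 * 5), 30, 5)
  fit <- cca_fit(X, Z, r_cc = 3)
  idx <- c(2, 9, 17)
  expect_equal(
    cc_scores(fit, X, 1)[idx, ],
    cc_scores(fit, X[idx, , drop = FALSE], 1),
    tolerance = 1e-12
  )
  # a row equal to the centering vector scores zero
  expect_equal(
    as.numeric(cc_scores(fit, matrix(fit$center_1, 1), 1)),
    rep(0, 3), tolerance = 1e-12
  )
  expect_error(cc_scores(fit, Z, 1), "expects")

  # identical-data pivots give equal scores on both sides
  same <- cca_fit(X, X, r_cc = 3, ridge = 0)
  expect_equal(cc_scores(same, X, 1), cc_scores(same, X, 2),
    tolerance = 1e-8)
})

test_that("gCCA reduces to CCA when a view is duplicated", {
  set.seed(7)
  X <- matrix(rnorm(200 * 3), 200, 3)
  Z <- X %*% matrix(rnorm(9), 3) + 0.5 * matrix(rnorm(200 * 3), 200, 3)
  cc <- cca_fit(X, Z, r_cc = 3, ridge = 0)
  g <- gcca_fit(list(X, Z, Z), r = 3, ridge = 0)
  p1 <- gcca_scores(g, X, 1)
  p2 <- gcca_scores(g, Z, 2)
  pair_cor <- vapply(1:3, function(j) abs(cor(p1[, j], p2[, j])), numeric(1))
  expect_equal(pair_cor, cc$correlations, tolerance = 1e-6)

  # three identical views are mutually correlated at one
  g3 <- gcca_fit(list(X, X, X), r = 3, ridge = 0)
  expect_equal(g3$correlations, rep(1, 3), tolerance = 1e-8)
})

test_that("gCCA recovers a shared one-dimensional signal from noisy views", {
  set.seed(8)
  n <- 300
  shared <- rnorm(n)
  views <- lapply(1:3, function(i) {
    cbind(shared + 0.3 * rnorm(n), rnorm(n), rnorm(n))
  })
  g <- gcca_fit(views, r = 1)
  proj <- gcca_scores(g, views[[1]], 1)
  expect_gt(abs(cor(proj[, 1], shared)), 0.9)
})
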