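# Shared fixture builders. All fixtures are generated in code.

toy_dataset <- function(n = 6, p = 4, seed = 1, prefix = "f") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p)
  modality_dataset(m,
    cell_ids = paste0("c", seq_len(n)),
    feature_ids = paste0(prefix, seq_len(p))
  )
}

# two well-separated Gaussian blobs, n_per cells each; the second blob is
# shifted on alternating features only, so the blobs differ in profile
# shape (visible to both euclidean and correlation distances)
blob_pair <- function(n_per = 10, p = 5, sep = 20, seed = 1) {
  set.seed(seed)
  shift <- rep(c(sep, 0), length.out = p)
  m <- rbind(
    matrix(rnorm(n_per * p), n_per, p),
    matrix(rnorm(n_per * p), n_per, p) +
      matrix(shift, n_per, p, byrow = TRUE)
  )
  list(matrix = m, labels = rep(c(1L, 2L), each = n_per))
}

# brute-force minimum-cost assignment by enumeration (oracle)
brute_force_lap <- function(D) {
  nr <- nrow(D)
  nc <- ncol(D)
  if (nr <= nc) {
    cols <- seq_len(nc)
    best <- Inf
    rec <- function(row, used, acc) {
      if (acc >= best) return(invisible())
      if (row > nr) {
        best <<- min(best, acc)
        return(invisible())
      }
      for (j in cols[!used]) {
        used[j] <- TRUE
        rec(row + 1L, used, acc + D[row, j])
        used[j] <- FALSE
      }
    }
    rec(1L, rep(FALSE, nc), 0)
    best
  } else {
    brute_force_lap(t(D))
  }
}

# double-loop FOSCTTM oracle (integer counts, single final division)
foscttm_oracle <- function(e1, e2) {
  N <- nrow(e1)
  tot <- 0L
  for (i in seq_len(N)) {
    d_true <- sqrt(sum((e1[i, ] - e2[i, ])^2))
    for (j in seq_len(N)) {
      if (sqrt(sum((e1[i, ] - e2[j, ])^2)) < d_true) tot <- tot + 1L
      if (sqrt(sum((e2[i, ] - e1[j, ])^2)) < d_true) tot <- tot + 1L
    }
  }
  tot / (2 * N^2)
}

# generalized-eigenvalue CCA oracle: canonical correlations only
cca_oracle <- function(x, z) {
  n <- nrow(x)
  xc <- scale(x, scale = FALSE)
  zc <- scale(z, scale = FALSE)
  Cxx <- crossprod(xc) / n
  Czz <- crossprod(zc) / n
  Cxz <- crossprod(xc, zc) / n
  M <- solve(Cxx) %*% Cxz %*% solve(Czz) %*% t(Cxz)
  ev <- eigen(M, only.values = TRUE)$values
  sqrt(pmax(pmin(Re(ev), 1), 0))
}

expect_match_equal <- function(a, b) {
  expect_identical(a$idx_1, b$idx_1)
  expect_identical(a$idx_2, b$idx_2)
}
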