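# Internal numerical helpers shared across modules.

# Population (divide-by-n) column standardization. Constant columns map to
# all zeros rather than NaN so downstream correlation/SVD steps stay finite.
zscore_cols <- function(A) {
  A <- as.matrix(A)
  mu <- colMeans(A)
  Ac <- sweep(A, 2L, mu, "-")
  s <- sqrt(colMeans(Ac^2))
  s[s == 0] <- Inf
  sweep(Ac, 2L, s, "/")
}

# Row standardization for fast row-wise Pearson via tcrossprod.
# Constant rows become all-zero rows (treated as correlation 0 downstream).
row_standardize <- function(A) {
  A <- as.matrix(A)
  mu <- rowMeans(A)
  Ac <- A - mu
  s <- sqrt(rowMeans(Ac^2))
  s[s == 0] <- Inf
  Ac / s
}

# Row-wise Pearson correlation between rows of A and rows of B.
rowwise_cor <- function(A, B) {
  if (ncol(A) != ncol(B)) {
    abort("matrices must have the same number of columns")
  }
  tcrossprod(row_standardize(A), row_standardize(B)) / ncol(A)
}

# Pearson correlation between paired rows A[i, ] and B[i, ].
paired_row_cor <- function(A, B) {
  stopifnot(nrow(A) == nrow(B), ncol(A) == ncol(B))
  rowSums(row_standardize(A) * row_standardize(B)) / ncol(A)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_range <- function(x, name, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf(
      "`%s` must be in %s%g, %g%s", name,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
    ))
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
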