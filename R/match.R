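# Cross-modal distances, SVD projection and minimum-cost linear assignment.

new_match_table <- function(idx_1, idx_2, distance = NA_real_,
                            score = NA_real_, provenance = "initial",
                            level = "metacell") {
  out <- tibble(
    idx_1 = as.integer(idx_1), idx_2 = as.integer(idx_2),
    distance = as.double(distance), score = as.double(score),
    provenance = provenance, level = level
  )
  class(out) <- c("match_table", class(out))
  out
}

#' Project a matrix onto its leading singular subspace
#'
#' Column-centers `A` and returns the first `r` left singular vectors scaled
#' by their singular values (`U_r %*% diag(s_r)`), i.e. the coordinates of
#' the rows in the leading rank-`r` subspace. Signs are fixed so that the
#' largest-magnitude entry of each right singular vector is positive, making
#' runs reproducible across LAPACK implementations.
#'
#' @param A Numeric matrix (n x m).
#' @param r Number of components, `1 <= r <= min(n, m)`.
#' @return n x r score matrix.
#' @export
svd_project <- function(A, r) {
  A <- as.matrix(A)
  r <- check_count(r, "r")
  if (r > min(dim(A))) {
    abort(sprintf(
      "r = %d exceeds min(dim(A)) = %d", r, min(dim(A))
    ))
  }
  Ac <- sweep(A, 2L, colMeans(A), "-")
  sv <- svd(Ac, nu = r, nv = r)
  flip <- vapply(seq_len(r), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sv$u * rep(sv$d[seq_len(r)] * flip, each = nrow(A))
  colnames(scores) <- paste0("sv", seq_len(r))
  scores
}

#' Rank-r denoising by projection onto the leading singular subspace
#'
#' Column-centers `A`, keeps its rank-`r` truncated SVD, and adds the
#' column means back: each row is replaced by its projection onto the
#' leading singular subspace, expressed in the original feature
#' coordinates. Unlike [svd_project()] scores, the output lives in the same
#' feature space as the input, so denoised matrices from two modalities
#' with corresponding columns remain directly comparable.
#'
#' @inheritParams svd_project
#' @return Matrix of the same dimension as `A`.
#' @export
svd_denoise <- function(A, r) {
  A <- as.matrix(A)
  r <- check_count(r, "r")
  if (r > min(dim(A))) {
    abort(sprintf("r = %d exceeds min(dim(A)) = %d", r, min(dim(A))))
  }
  mu <- colMeans(A)
  Ac <- sweep(A, 2L, mu, "-")
  sv <- svd(Ac, nu = r, nv = r)
  rec <- sv$u %*% (t(sv$v) * sv$d[seq_len(r)])
  sweep(rec, 2L, mu, "+")
}

#' Pairwise cross-modal distances
#'
#' @param A,B Numeric matrices with equal column counts (rows are cells).
#' @param metric `"correlation"` gives `1 - Pearson(A[i, ], B[j, ])` (range
#'   \[0, 2\]; rows with zero variance are treated as uncorrelated), and
#'   `"euclidean"` the L2 distance.
#' @return An `n_A` x `n_B` matrix.
#' @export
cross_distance <- function(A, B, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (ncol(A) != ncol(B)) {
    abort(sprintf(
      "column mismatch: A has %d, B has %d columns", ncol(A), ncol(B)
    ))
  }
  if (metric == "correlation") {
    if (ncol(A) < 2L) {
      abort("correlation distance requires at least 2 columns")
    }
    D <- 1 - rowwise_cor(A, B)
    # clamp tiny numerical excursions outside [0, 2]
    D[D < 0] <- 0
    D[D > 2] <- 2
  } else {
    an <- rowSums(A^2)
    bn <- rowSums(B^2)
    D2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
    # Gram-based squared distances can go (tiny) negative or leave
    # floating-point residue where rows coincide; snap those to zero
    D2[D2 < 64 * .Machine$double.eps * outer(an, bn, "+")] <- 0
    D <- sqrt(D2)
  }
  D
}

#' Minimum-cost linear assignment
#'
#' Solves the rectangular assignment problem: selects
#' `n_min = min(nrow(D), ncol(D))` entries of the cost matrix, at most one
#' per row and per column, minimizing the total cost. Solved exactly by a
#' shortest-augmenting-path (Jonker-Volgenant) algorithm implemented in C++.
#'
#' @param D Finite numeric cost matrix.
#' @return A `match_table` tibble with `n_min` rows (`idx_1`, `idx_2`,
#'   `distance`) and attribute `objective`, the minimal total cost.
#' @examples
#' linear_assignment(rbind(c(1, 2, 3), c(2, 4, 1)))
#' @export
linear_assignment <- function(D) {
  D <- as.matrix(D)
  if (length(D) == 0L) abort("empty cost matrix")
  if (!all(is.finite(D))) abort("cost matrix must be finite")
  transposed <- nrow(D) > ncol(D)
  sol <- if (transposed) lap_solve_cpp(t(D)) else lap_solve_cpp(D)
  if (transposed) {
    idx_1 <- sol$assignment
    idx_2 <- seq_len(ncol(D))
  } else {
    idx_1 <- seq_len(nrow(D))
    idx_2 <- sol$assignment
  }
  out <- new_match_table(idx_1, idx_2,
    distance = D[cbind(idx_1, idx_2)],
    provenance = "initial"
  )
  attr(out, "objective") <- sol$objective
  out
}

#' Initial cross-modal matching on smoothed linked features
#'
#' Projects each side onto its leading singular subspace (rank-`svd1` /
#' `svd2` denoising via [svd_denoise()], which keeps the shared
#' linked-feature coordinates so the two sides remain comparable), computes
#' the cross-modal distance matrix, and solves the linear assignment. The
#' resulting pairs are the initial pivots.
#'
#' @param linked_1,linked_2 Smoothed linked-feature matrices sharing `s`
#'   columns.
#' @param svd1,svd2 Components per side; `NULL` uses `min(30, s)`. Values
#'   are capped at each matrix's feasible rank.
#' @param metric Distance metric, see [cross_distance()].
#' @return A `match_table` with `n_min` rows, `provenance = "initial"` and
#'   attribute `objective`.
#' @export
initial_match <- function(linked_1, linked_2, svd1 = NULL, svd2 = NULL,
                          metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  s <- ncol(linked_1)
  if (ncol(linked_2) != s) abort("linked matrices must share columns")
  r1 <- min(svd1 %||% min(30L, s), dim(linked_1))
  r2 <- min(svd2 %||% min(30L, s), dim(linked_2))
  d1 <- svd_denoise(linked_1, r1)
  d2 <- svd_denoise(linked_2, r2)
  D <- cross_distance(d1, d2, metric = metric)
  linear_assignment(D)
}

#' Matching in random batches for large inputs
#'
#' Partitions the larger side into random batches of at most `batch_size`
#' rows (seeded), matches each batch against the full smaller side by linear
#' assignment, and concatenates the pairs. Rows of the smaller side may be
#' matched by several batches; such duplicates are resolved later by
#' scoring/pruning.
#'
#' @param score_1,score_2 Row-coordinate matrices for the two sides (same
#'   column count), e.g. smoothed SVD/CCA scores.
#' @param batch_size Maximum batch size (>= 2); `Inf` reduces to a single
#'   assignment.
#' @param metric See [cross_distance()].
#' @param seed Integer seed for the random partition.
#' @return A `match_table` covering every row of the larger side, with
#'   attribute `objective` (sum over batches).
#' @export
batched_match <- function(score_1, score_2, batch_size = Inf,
                          metric = c("correlation", "euclidean"),
                          seed = 42) {
  metric <- match.arg(metric)
  n1 <- nrow(score_1)
  n2 <- nrow(score_2)
  larger_is_1 <- n1 >= n2
  n_big <- max(n1, n2)
  if (is.infinite(batch_size) || batch_size >= n_big) {
    D <- cross_distance(score_1, score_2, metric = metric)
    return(linear_assignment(D))
  }
  check_count(batch_size, "batch_size", min = 2L)
  set.seed(seed)
  perm <- sample.int(n_big)
  n_batches <- ceiling(n_big / batch_size)
  groups <- split(perm, rep(seq_len(n_batches), length.out = n_big))
  pieces <- vector("list", n_batches)
  objective <- 0
  for (b in seq_len(n_batches)) {
    rows <- sort(groups[[b]])
    if (larger_is_1) {
      D <- cross_distance(score_1[rows, , drop = FALSE], score_2,
        metric = metric
      )
      mt <- linear_assignment(D)
      mt$idx_1 <- rows[mt$idx_1]
    } else {
      D <- cross_distance(score_1, score_2[rows, , drop = FALSE],
        metric = metric
      )
      mt <- linear_assignment(D)
      mt$idx_2 <- rows[mt$idx_2]
    }
    objective <- objective + attr(mt, "objective")
    pieces[[b]] <- mt
  }
  out <- bind_rows(pieces)
  out <- arrange(out, .data$idx_1, .data$idx_2)
  class(out) <- c("match_table", class(out))
  attr(out, "objective") <- objective
  out
}
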