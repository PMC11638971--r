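#' Build a self-inclusive nearest-neighbor graph
#'
#' Each row is connected to its `k` nearest rows *including itself*; the
#' adjacency is binary and not symmetrized (row degrees are exactly `k`,
#' column degrees may vary). Ties are broken towards the lower row index;
#' the self edge is always present.
#'
#' @param matrix Numeric matrix, observations in rows.
#' @param k Neighborhood size including self, `2 <= k <= nrow(matrix)`
#'   (`k = 1` gives the identity graph).
#' @param metric `"correlation"` (1 - Pearson between rows) or
#'   `"euclidean"`.
#' @return An object of class `nn_graph`: list with sparse binary
#'   `adjacency` (n x n, `Matrix::dgCMatrix`) and integer `degrees`.
#' @examples
#' g <- build_nn_graph(matrix(c(0, 1, 10), ncol = 1), k = 2,
#'                     metric = "euclidean")
#' as.matrix(g$adjacency)
#' @export
build_nn_graph <- function(matrix,
                           metric = c("correlation", "euclidean"), k = 15) {
  metric <- match.arg(metric)
  m <- as.matrix(matrix)
  n <- nrow(m)
  k <- check_count(k, "k")
  if (k > n) abort(sprintf("k = %d exceeds the number of rows (%d)", k, n))
  D <- cross_distance(m, m, metric = metric)
  idx <- integer(0)
  jdx <- integer(0)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- -Inf # self always first
    nb <- order(d, seq_len(n))[seq_len(k)] # ties -> lower index
    idx <- c(idx, rep.int(i, k))
    jdx <- c(jdx, nb)
  }
  adj <- Matrix::sparseMatrix(i = idx, j = jdx, x = 1, dims = c(n, n))
  structure(
    list(adjacency = adj, degrees = rep.int(k, n), metric = metric),
    class = "nn_graph"
  )
}

#' @export
print.nn_graph <- function(x, ...) {
  cat(sprintf(
    "<nn_graph> %d nodes, row degree %s, metric %s\n",
    length(x$degrees), paste(unique(x$degrees), collapse = "/"), x$metric
  ))
  invisible(x)
}

#' Fuzzy smoothing over a nearest-neighbor graph
#'
#' Shrinks each row of `A` towards the mean of its graph neighborhood
#' (self included): returns `w * A + (1 - w) * K^{-1} G A`, where `G` is the
#' binary adjacency and `K` the diagonal of row degrees. `w = 1` returns `A`
#' unchanged; `w = 0` returns pure neighborhood means.
#'
#' @param A Numeric matrix with one row per graph node.
#' @param graph An [build_nn_graph()] result (or any list with binary
#'   `adjacency` and `degrees`).
#' @param w Weight on the unsmoothed matrix, in \[0, 1\].
#' @return Matrix of the same dimension as `A`.
#' @export
fuzzy_smooth <- function(A, graph, w) {
  A <- as.matrix(A)
  check_range(w, "w", 0, 1)
  n <- length(graph$degrees)
  if (nrow(A) != n) {
    abort(sprintf(
      "A has %d rows but the graph has %d nodes", nrow(A), n
    ))
  }
  if (w == 1) {
    return(A)
  }
  nbhd_mean <- as.matrix(graph$adjacency %*% A) / graph$degrees
  w * A + (1 - w) * nbhd_mean
}
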