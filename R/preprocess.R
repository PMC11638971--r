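# Meta-cell construction: Leiden communities on an all-feature k-NN graph,
# with the resolution tuned by bisection so the mean community size hits a
# user-facing target.

#' Aggregate cells into meta-cells
#'
#' Builds a k-NN graph on the PCA-reduced all-feature matrix, runs Leiden
#' community detection, and tunes the resolution by bisection until the
#' number of communities `n_meta` falls within
#' `[N/(size + 0.5), N/(size - 0.5)]` (or 20 bisection steps elapse). Member
#' rows of both the all-feature matrix and, if given, the linked-feature
#' matrix are then averaged. Small targets (2-3 cells per meta-cell) denoise
#' sparse data while nearly preserving resolution.
#'
#' @param dataset A [modality_dataset()].
#' @param linked_matrix Optional N x s linked-feature matrix to aggregate
#'   with the same clustering.
#' @param target_size Desired mean meta-cell size; `1` (or `"off"`) returns
#'   the identity map.
#' @param k_nn Neighborhood size of the graph (must be < N).
#' @param r_pca Principal components used for the graph (capped at
#'   `min(p, N - 1)`).
#' @param seed Integer seed (Leiden refinement is stochastic).
#' @return Object of class `metacell_map`: list with integer `assignment`
#'   (length N, values in `1..n_meta`), `n_meta`, `sizes`, `all_means`
#'   (n_meta x p) and `linked_means` (n_meta x s or NULL).
#' @export
build_metacells <- function(dataset, linked_matrix = NULL, target_size = 2,
                            k_nn = 15, r_pca = 30, seed = 42) {
  stopifnot(inherits(dataset, "modality_dataset"))
  if (identical(target_size, "off")) target_size <- 1
  check_range(target_size, "target_size", 1, Inf)
  N <- nrow(dataset$matrix)
  if (!is.null(linked_matrix) && nrow(linked_matrix) != N) {
    abort("linked_matrix must have one row per cell")
  }

  if (target_size <= 1) {
    return(structure(
      list(
        assignment = seq_len(N), n_meta = N, sizes = rep.int(1L, N),
        all_means = dataset$matrix,
        linked_means = if (is.null(linked_matrix)) NULL else
          as.matrix(linked_matrix)
      ),
      class = "metacell_map"
    ))
  }
  if (k_nn >= N) {
    abort(sprintf("k_nn = %d must be smaller than the cell count %d", k_nn, N))
  }

  r <- min(r_pca, ncol(dataset$matrix), N - 1L)
  scores <- pca_reduce(zscore_cols(dataset$matrix), r)
  g <- build_nn_graph(scores, metric = "euclidean", k = k_nn)
  adj <- g$adjacency
  diag(adj) <- 0
  ig <- igraph::graph_from_adjacency_matrix(adj,
    mode = "max", weighted = NULL, diag = FALSE
  )

  lo_n <- N / (target_size + 0.5)
  hi_n <- N / (target_size - 0.5)
  run_leiden <- function(res) {
    set.seed(seed)
    igraph::membership(igraph::cluster_leiden(
      ig,
      objective_function = "modularity",
      resolution = res, n_iterations = 3
    ))
  }
  lo_r <- 1e-3
  hi_r <- 1
  memb <- run_leiden(hi_r)
  tries <- 0L
  while (max(memb) < lo_n && tries < 30L) {
    hi_r <- hi_r * 2
    memb <- run_leiden(hi_r)
    tries <- tries + 1L
  }
  best <- memb
  if (max(memb) > hi_n) {
    for (step in seq_len(20L)) {
      mid <- (lo_r + hi_r) / 2
      memb <- run_leiden(mid)
      nm <- max(memb)
      best <- memb
      if (nm >= lo_n && nm <= hi_n) break
      if (nm > hi_n) hi_r <- mid else lo_r <- mid
    }
  }
  assignment <- as.integer(factor(best)) # densify labels
  n_meta <- max(assignment)
  sizes <- tabulate(assignment, n_meta)

  all_means <- rowsum(dataset$matrix, assignment) / sizes
  linked_means <- if (is.null(linked_matrix)) NULL else
    rowsum(as.matrix(linked_matrix), assignment) / sizes
  rownames(all_means) <- NULL
  if (!is.null(linked_means)) rownames(linked_means) <- NULL

  structure(
    list(
      assignment = assignment, n_meta = n_meta, sizes = sizes,
      all_means = all_means, linked_means = linked_means
    ),
    class = "metacell_map"
  )
}

#' @export
print.metacell_map <- function(x, ...) {
  cat(sprintf(
    "<metacell_map> %d cells -> %d meta-cells (mean size %.2f)\n",
    length(x$assignment), x$n_meta, mean(x$sizes)
  ))
  invisible(x)
}
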