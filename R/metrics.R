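# Evaluation criteria for diagonal integration: cell-type matching
# accuracy, FOSCTTM, FOSKNN, Silhouette F1 and ARI F1, plus the
# nearest-neighbor match extraction used to evaluate embeddings.

#' Cell-type matching accuracy
#'
#' Fraction of matched pairs whose two cells carry identical cell-type
#' annotations.
#'
#' @param matching A `match_table` (columns `idx_1`, `idx_2`).
#' @param labels_1,labels_2 Per-cell annotation vectors for the two
#'   modalities, indexed by `idx_1` / `idx_2`.
#' @return A single fraction in \[0, 1\].
#' @export
matching_accuracy <- function(matching, labels_1, labels_2) {
  if (nrow(matching) == 0L) {
    abort("matching accuracy is undefined for an empty pair list")
  }
  l1 <- labels_1[matching$idx_1]
  l2 <- labels_2[matching$idx_2]
  if (anyNA(l1)) {
    abort(sprintf(
      "missing label for modality-1 index %d",
      matching$idx_1[which(is.na(l1))[1]]
    ))
  }
  if (anyNA(l2)) {
    abort(sprintf(
      "missing label for modality-2 index %d",
      matching$idx_2[which(is.na(l2))[1]]
    ))
  }
  mean(l1 == l2)
}

#' Nearest-neighbor matching from a joint embedding
#'
#' For each cell on the query side, pairs it with its nearest neighbor on
#' the other side under Pearson correlation distance in the embedding.
#'
#' @param emb_1,emb_2 Embedding matrices with equal column count (>= 2).
#' @param direction `"1_to_2"`: each modality-1 cell queries modality 2;
#'   `"2_to_1"` the reverse.
#' @return A `match_table` with one row per query cell.
#' @export
knn_match_from_embedding <- function(emb_1, emb_2,
                                     direction = c("1_to_2", "2_to_1")) {
  direction <- match.arg(direction)
  D <- cross_distance(emb_1, emb_2, metric = "correlation")
  if (direction == "1_to_2") {
    nn <- max.col(-D, ties.method = "first")
    out <- new_match_table(seq_len(nrow(D)), nn,
      distance = D[cbind(seq_len(nrow(D)), nn)],
      provenance = "initial", level = "singlecell"
    )
  } else {
    nn <- max.col(-t(D), ties.method = "first")
    out <- new_match_table(nn, seq_len(ncol(D)),
      distance = D[cbind(nn, seq_len(ncol(D)))],
      provenance = "initial", level = "singlecell"
    )
  }
  out
}

#' Fraction of samples closer than the true match (FOSCTTM)
#'
#' Rows of the two embeddings must be aligned so that row i of `emb_1` and
#' row i of `emb_2` are the same cell measured in the two modalities. For
#' each cell, the fraction of opposite-modality cells lying strictly closer
#' than its true match is computed; FOSCTTM averages this fraction over all
#' cells in both directions. 0 indicates a perfect embedding; independent
#' embeddings give about 0.5.
#'
#' @param emb_1,emb_2 Row-aligned embedding matrices (N x r each).
#' @param metric Distance in the embedding space: `"euclidean"` (default)
#'   or `"correlation"`.
#' @return Value in `[0, (N - 1)/N]`.
#' @export
foscttm <- function(emb_1, emb_2, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  if (nrow(emb_1) != nrow(emb_2)) {
    abort("FOSCTTM requires a ground-truth pairing: equal row counts")
  }
  N <- nrow(emb_1)
  D <- cross_distance(emb_1, emb_2, metric = metric)
  d_true <- diag(D)
  count_1 <- rowSums(D < d_true)                # closer than true, side 1
  count_2 <- colSums(D < rep(d_true, each = N)) # side 2
  (sum(count_1) + sum(count_2)) / (2 * N^2)
}

#' Fraction of samples whose true match is among the k nearest neighbors
#'
#' @inheritParams foscttm
#' @param k Neighborhood size(s), `1 <= k <= N`; may be a vector.
#' @return Numeric vector of fractions, one per `k`, nondecreasing in `k`.
#' @export
fosknn <- function(emb_1, emb_2, k = 1,
                   metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  if (nrow(emb_1) != nrow(emb_2)) {
    abort("FOSKNN requires a ground-truth pairing: equal row counts")
  }
  N <- nrow(emb_1)
  k <- vapply(k, check_count, integer(1), name = "k")
  if (any(k > N)) abort("k must not exceed the number of cells")
  D <- cross_distance(emb_1, emb_2, metric = metric)
  d_true <- diag(D)
  # rank of the true match = 1 + number of strictly closer cells
  rank_1 <- rowSums(D < d_true) + 1L
  rank_2 <- colSums(D < rep(d_true, each = N)) + 1L
  vapply(
    k, function(kk) (mean(rank_1 <= kk) + mean(rank_2 <= kk)) / 2,
    numeric(1)
  )
}

normalized_silhouette <- function(emb, labels) {
  lab <- as.integer(factor(labels))
  if (length(unique(lab)) < 2L) {
    abort("silhouette width is undefined with a single label level")
  }
  sil <- cluster::silhouette(lab, stats::dist(emb))
  (mean(sil[, "sil_width"]) + 1) / 2
}

#' Silhouette F1 score of a joint embedding
#'
#' Harmonic mean of `slt_mix`, one minus the normalized average silhouette
#' width with modality as the label (rewards mixing of modalities), and
#' `slt_clust`, the normalized average silhouette width with cell type as
#' the label (rewards preservation of biology). Widths are mapped from
#' \[-1, 1\] to \[0, 1\] via `(x + 1)/2`.
#'
#' @param emb_joint Pooled embedding (rows of both modalities stacked).
#' @param modality_labels Modality indicator per row.
#' @param celltype_labels Cell-type annotation per row (>= 2 types).
#' @return List with `slt_mix`, `slt_clust`, `f1`.
#' @export
silhouette_f1 <- function(emb_joint, modality_labels, celltype_labels) {
  slt_mix <- 1 - normalized_silhouette(emb_joint, modality_labels)
  slt_clust <- normalized_silhouette(emb_joint, celltype_labels)
  f1 <- if (slt_mix + slt_clust == 0) 0 else
    2 * slt_mix * slt_clust / (slt_mix + slt_clust)
  list(slt_mix = slt_mix, slt_clust = slt_clust, f1 = f1)
}

#' ARI F1 score of a joint embedding
#'
#' k-means clusters the pooled embedding (k = number of cell types, seeded,
#' 10 restarts); `ari_clust` is the adjusted Rand index between clusters and
#' cell types (clipped to \[0, 1\]) and `ari_mix` is one minus the absolute
#' ARI between clusters and modality (clipped likewise), so that clusters
#' tracking modality rather than biology drive the F1 towards zero.
#'
#' @inheritParams silhouette_f1
#' @param n_clusters Number of k-means clusters; default the number of cell
#'   types.
#' @param seed Integer seed for k-means restarts.
#' @return List with `ari_mix`, `ari_clust`, `f1`.
#' @export
ari_f1 <- function(emb_joint, modality_labels, celltype_labels,
                   n_clusters = NULL, seed = 42) {
  if (length(unique(celltype_labels)) < 2L) {
    abort("ARI F1 requires at least two cell types")
  }
  k <- n_clusters %||% length(unique(celltype_labels))
  set.seed(seed)
  cl <- stats::kmeans(emb_joint, centers = k, nstart = 10, iter.max = 50)
  ari_clust <- min(max(
    mclust::adjustedRandIndex(cl$cluster, celltype_labels), 0
  ), 1)
  ari_mix <- min(max(
    1 - abs(mclust::adjustedRandIndex(cl$cluster, modality_labels)), 0
  ), 1)
  f1 <- if (ari_mix + ari_clust == 0) 0 else
    2 * ari_mix * ari_clust / (ari_mix + ari_clust)
  list(ari_mix = ari_mix, ari_clust = ari_clust, f1 = f1)
}

#' Evaluate an integration result
#'
#' Bundles every applicable criterion into one report: cell-type matching
#' accuracy of the match table, Silhouette F1 and ARI F1 of the pooled
#' embedding, and — when a ground-truth pairing is supplied — FOSCTTM and
#' FOSKNN.
#'
#' @param matching A `match_table`.
#' @param emb_1,emb_2 Final joint embeddings.
#' @param celltypes_1,celltypes_2 Per-cell annotations.
#' @param truth_pairing Optional two-column table (`idx_1`, `idx_2`) of
#'   ground-truth pairs used to align the embeddings for FOSCTTM/FOSKNN.
#' @param k Neighborhood sizes for FOSKNN.
#' @param seed Seed for the ARI k-means.
#' @return A one-row tibble of metric values.
#' @export
evaluate_integration <- function(matching, emb_1, emb_2,
                                 celltypes_1, celltypes_2,
                                 truth_pairing = NULL, k = 1, seed = 42) {
  emb_joint <- rbind(emb_1, emb_2)
  modality <- rep(c("mod1", "mod2"), c(nrow(emb_1), nrow(emb_2)))
  celltype <- c(celltypes_1, celltypes_2)
  slt <- silhouette_f1(emb_joint, modality, celltype)
  ari <- ari_f1(emb_joint, modality, celltype, seed = seed)
  out <- tibble(
    accuracy = matching_accuracy(matching, celltypes_1, celltypes_2),
    slt_f1 = slt$f1, slt_mix = slt$slt_mix, slt_clust = slt$slt_clust,
    ari_f1 = ari$f1, ari_mix = ari$ari_mix, ari_clust = ari$ari_clust
  )
  if (!is.null(truth_pairing)) {
    e1 <- emb_1[truth_pairing$idx_1, , drop = FALSE]
    e2 <- emb_2[truth_pairing$idx_2, , drop = FALSE]
    out$foscttm <- foscttm(e1, e2)
    kn <- fosknn(e1, e2, k = k)
    for (i in seq_along(k)) out[[paste0("fosknn_k", k[i])]] <- kn[i]
  }
  out
}
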