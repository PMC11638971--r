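# Pipeline orchestration: initialization, iterative refinement, pivot
# filtering, final joint embedding, propagation, expansion, scoring and
# pruning.

#' Filter matched pairs down to refined pivots
#'
#' Ranks the pairs by distance and keeps the `ceiling((1 - alpha) * n)`
#' closest ones, which serve as refined pivots for the final embedding and
#' for match propagation. `alpha = 0` (the default filtering proportion)
#' keeps every pair.
#'
#' @param match_table A `match_table` tibble with a `distance` column.
#' @param alpha Filtering proportion in \[0, 1).
#' @return The retained rows with `provenance = "refined_pivot"`.
#' @export
filter_pivots <- function(match_table, alpha = 0) {
  check_range(alpha, "alpha", 0, 1, hi_open = TRUE)
  n_keep <- ceiling((1 - alpha) * nrow(match_table))
  out <- match_table[order(match_table$distance,
    match_table$idx_1, match_table$idx_2
  )[seq_len(n_keep)], , drop = FALSE]
  out <- arrange(out, .data$idx_1, .data$idx_2)
  out$provenance <- "refined_pivot"
  class(out) <- unique(c("match_table", class(out)))
  out
}

#' Propagate pivot matches to unmatched cells
#'
#' For every row of a modality that is not part of any pivot, finds its
#' nearest within-modality neighbor among pivot members (on the smoothed
#' all-feature coordinates) and inherits that pivot's partner from the other
#' modality. Pairs whose nearest-neighbor distance exceeds the given
#' percentile of all such distances (per direction) are dropped. Both
#' directions are run.
#'
#' @param pivots A `match_table` of refined pivots (meta-cell level).
#' @param smoothed_1,smoothed_2 Smoothed all-feature matrices of the two
#'   modalities (one row per meta-cell).
#' @param metric Within-modality distance metric.
#' @param percentile Distance-threshold percentile in \[0, 100\]; 100 keeps
#'   every propagated pair.
#' @return A `match_table` with `provenance = "propagated"`; `distance` is
#'   the within-modality nearest-pivot distance.
#' @export
propagate_matches <- function(pivots, smoothed_1, smoothed_2,
                              metric = c("correlation", "euclidean"),
                              percentile = 100) {
  metric <- match.arg(metric)
  check_range(percentile, "percentile", 0, 100)
  if (nrow(pivots) == 0L) abort("pivot set is empty")

  one_direction <- function(S, members, partners, n) {
    unmatched <- setdiff(seq_len(n), members)
    if (length(unmatched) == 0L) {
      return(tibble(
        own = integer(0), partner = integer(0), distance = numeric(0)
      ))
    }
    D <- cross_distance(S[unmatched, , drop = FALSE],
      S[members, , drop = FALSE],
      metric = metric
    )
    nn <- max.col(-D, ties.method = "first")
    d_nn <- D[cbind(seq_along(unmatched), nn)]
    thr <- stats::quantile(d_nn, percentile / 100, names = FALSE, type = 7)
    keep <- d_nn <= thr
    tibble(
      own = unmatched[keep], partner = partners[nn[keep]],
      distance = d_nn[keep]
    )
  }

  p1 <- one_direction(
    smoothed_1, pivots$idx_1, pivots$idx_2, nrow(smoothed_1)
  )
  p2 <- one_direction(
    smoothed_2, pivots$idx_2, pivots$idx_1, nrow(smoothed_2)
  )
  out <- bind_rows(
    new_match_table(p1$own, p1$partner,
      distance = p1$distance, provenance = "propagated"
    ),
    new_match_table(p2$partner, p2$own,
      distance = p2$distance, provenance = "propagated"
    )
  )
  class(out) <- unique(c("match_table", class(out)))
  out
}

#' Expand a meta-cell matching to single cells
#'
#' Every pair of matched meta-cells contributes the Cartesian product of
#' their member cells as candidate single-cell pairs.
#'
#' @param meta_matches A meta-cell-level `match_table`.
#' @param map_1,map_2 [build_metacells()] results (or NULL for an identity
#'   map on either side).
#' @return A `match_table` with `level = "singlecell"`; `distance` and
#'   `provenance` are inherited from the meta-cell pair.
#' @export
expand_to_single_cells <- function(meta_matches, map_1 = NULL, map_2 = NULL) {
  members <- function(map) {
    if (is.null(map)) {
      return(NULL)
    }
    split(seq_along(map$assignment), map$assignment)
  }
  mem1 <- members(map_1)
  mem2 <- members(map_2)
  pieces <- vector("list", nrow(meta_matches))
  for (r in seq_len(nrow(meta_matches))) {
    a <- meta_matches$idx_1[r]
    b <- meta_matches$idx_2[r]
    cells_a <- if (is.null(mem1)) a else mem1[[as.character(a)]]
    cells_b <- if (is.null(mem2)) b else mem2[[as.character(b)]]
    grid <- expand.grid(
      idx_1 = cells_a, idx_2 = cells_b,
      KEEP.OUT.ATTRS = FALSE
    )
    pieces[[r]] <- new_match_table(grid$idx_1, grid$idx_2,
      distance = meta_matches$distance[r],
      provenance = meta_matches$provenance[r], level = "singlecell"
    )
  }
  out <- bind_rows(pieces)
  class(out) <- unique(c("match_table", class(out)))
  out
}

#' Score matched pairs and optionally prune per direction
#'
#' Scores each pair by the Pearson correlation of the corresponding rows of
#' the final joint embeddings. With directional pruning, each cell on the
#' pruned side retains only its highest-scoring pair (ties towards the
#' lower partner index); cells with no candidate pair remain unmatched.
#'
#' @param pairs A `match_table` of single-cell pairs.
#' @param emb_1,emb_2 Final joint embeddings (N1 x r_e, N2 x r_e, r_e >= 2).
#' @param direction `"none"`, `"1_to_2"` (one best match per modality-1
#'   cell) or `"2_to_1"`.
#' @return The scored (and possibly pruned) `match_table`.
#' @export
score_and_prune <- function(pairs, emb_1, emb_2,
                            direction = c("none", "1_to_2", "2_to_1")) {
  direction <- match.arg(direction)
  if (ncol(emb_1) < 2L || ncol(emb_2) < 2L) {
    abort("Pearson scoring requires embeddings with at least 2 columns")
  }
  pairs <- mutate(pairs, score = unname(paired_row_cor(
    emb_1[.data$idx_1, , drop = FALSE],
    emb_2[.data$idx_2, , drop = FALSE]
  )))
  if (direction != "none") {
    key <- if (direction == "2_to_1") "idx_2" else "idx_1"
    other <- if (direction == "2_to_1") "idx_1" else "idx_2"
    pairs <- pairs %>%
      group_by(.data[[key]]) %>%
      arrange(dplyr::desc(.data$score), .data[[other]], .by_group = TRUE) %>%
      dplyr::slice(1L) %>%
      ungroup() %>%
      arrange(.data$idx_1, .data$idx_2)
  }
  class(pairs) <- unique(c("match_table", class(pairs)))
  pairs
}

#' Chain two pivot sets through a shared modality
#'
#' Emits a triple `(a, b, c)` whenever `(a, b)` is a pivot between
#' modalities 1 and 2 and `(b, c)` is a pivot between modalities 2 and 3;
#' the shared modality-2 index is the intermediary and appears at most once
#' in the output.
#'
#' @param pivots_12,pivots_23 `match_table`s whose `idx_2` / `idx_1` columns
#'   refer to the shared modality with the same index space.
#' @return A tibble with columns `idx_1`, `idx_2`, `idx_3`.
#' @export
chain_pivots <- function(pivots_12, pivots_23) {
  ab <- distinct(
    tibble(idx_1 = pivots_12$idx_1, idx_2 = pivots_12$idx_2),
    .data$idx_2,
    .keep_all = TRUE
  )
  bc <- distinct(
    tibble(idx_2 = pivots_23$idx_1, idx_3 = pivots_23$idx_2),
    .data$idx_2,
    .keep_all = TRUE
  )
  out <- dplyr::inner_join(ab, bc, by = "idx_2")
  out <- select(out, "idx_1", "idx_2", "idx_3")
  if (nrow(out) == 0L) {
    warn("no chained pivots: the two pivot sets share no modality-2 index")
  }
  arrange(out, .data$idx_1)
}

#' Final joint embedding from refined pivots
#'
#' Fits a (ridge-regularized) CCA on the all-feature rows of the pivot
#' meta-cells and applies the learned loadings to every single cell of both
#' full matrices.
#'
#' @param all_1,all_2 Full single-cell all-feature matrices (standardized
#'   the same way as the meta-cell matrices).
#' @param meta_1,meta_2 Meta-cell all-feature matrices used to fit the CCA.
#' @param pivots Refined pivot `match_table` (meta-cell indices).
#' @param r_e Final embedding dimension (capped at the feasible rank).
#' @param ridge See [cca_fit()].
#' @param ridge_scale Shrinkage scale when `ridge` is `NULL`; the default
#'   `1` (canonical ridge, `lambda = trace(C)/dim` per side) is appropriate
#'   here because this CCA is fit on all features, whose count is often
#'   comparable to the pivot count, and lighter shrinkage overfits: it
#'   yields in-sample canonical correlations near one on components that
#'   carry no cross-modal signal, degrading the embedding for every cell.
#' @return List with `model` ([cca_fit()] object), `emb_1` (N1 x r_e) and
#'   `emb_2` (N2 x r_e).
#' @export
final_embedding <- function(all_1, all_2, meta_1, meta_2, pivots, r_e,
                            ridge = NULL, ridge_scale = 1) {
  r_eff <- min(r_e, ncol(meta_1), ncol(meta_2), nrow(pivots) - 1L)
  if (r_eff < 1L) abort("r_e is infeasible for the pivot count")
  model <- cca_fit(
    meta_1[pivots$idx_1, , drop = FALSE],
    meta_2[pivots$idx_2, , drop = FALSE],
    r_cc = r_eff, ridge = ridge, ridge_scale = ridge_scale
  )
  list(
    model = model,
    emb_1 = cc_scores(model, all_1, side = 1),
    emb_2 = cc_scores(model, all_2, side = 2)
  )
}

#' Match and coembed two modalities
#'
#' Runs the full cross-modal integration pipeline: internal per-feature
#' standardization, optional meta-cell aggregation, all-feature neighbor
#' graphs, fuzzy-smoothed linked-feature initialization, linear-assignment
#' matching with iterative CCA refinement, pivot filtering, final joint
#' embedding, match propagation, single-cell expansion, Pearson scoring and
#' optional directional pruning.
#'
#' @param dataset_1 The modality with the richer feature set / higher
#'   signal-to-noise ratio (e.g. RNA); meta-cells default on for this side.
#' @param dataset_2 The other modality (e.g. a targeted protein panel).
#' @param linkage A [linkage_map()] pairing features of the two sides.
#' @param config A [maxfuse_config()].
#' @return Object of class `maxfuse_fit`; see [tidy.maxfuse_fit()] for the
#'   single-cell match table, `$embeddings` for the final joint embeddings,
#'   `$pivots` for the refined meta-cell pivots and `$objectives` for the
#'   per-iteration assignment objective values.
#' @export
maxfuse_fit <- function(dataset_1, dataset_2, linkage,
                        config = maxfuse_config()) {
  stopifnot(
    inherits(dataset_1, "modality_dataset"),
    inherits(dataset_2, "modality_dataset"),
    inherits(config, "maxfuse_config")
  )
  set.seed(config$seed)
  linked <- make_linked_matrices(dataset_1, dataset_2, linkage)

  # internal standardization: per-feature population z-score
  all_1 <- zscore_cols(dataset_1$matrix)
  all_2 <- zscore_cols(dataset_2$matrix)
  lk_1 <- zscore_cols(linked$linked_1)
  lk_2 <- zscore_cols(linked$linked_2)

  map_1 <- build_metacells(
    modality_dataset(all_1, dataset_1$cell_ids, dataset_1$feature_ids),
    lk_1,
    target_size = config$metacell_size1, k_nn = config$k_nn1,
    r_pca = config$r1, seed = config$seed
  )
  map_2 <- build_metacells(
    modality_dataset(all_2, dataset_2$cell_ids, dataset_2$feature_ids),
    lk_2,
    target_size = config$metacell_size2, k_nn = config$k_nn2,
    r_pca = config$r2, seed = config$seed
  )
  meta_all_1 <- map_1$all_means
  meta_all_2 <- map_2$all_means
  meta_lk_1 <- zscore_cols(map_1$linked_means)
  meta_lk_2 <- zscore_cols(map_2$linked_means)
  n1 <- map_1$n_meta
  n2 <- map_2$n_meta

  # all-feature graphs on PCA scores
  r1_eff <- min(config$r1, ncol(meta_all_1), n1 - 1L)
  r2_eff <- min(config$r2, ncol(meta_all_2), n2 - 1L)
  scores_1 <- pca_reduce(meta_all_1, r1_eff)
  scores_2 <- pca_reduce(meta_all_2, r2_eff)
  g1 <- build_nn_graph(scores_1,
    metric = config$distance_metric,
    k = min(config$k_nn1, n1)
  )
  g2 <- build_nn_graph(scores_2,
    metric = config$distance_metric,
    k = min(config$k_nn2, n2)
  )

  # stage 1: smoothed linked features -> initial assignment
  sm_1 <- fuzzy_smooth(meta_lk_1, g1, config$w0)
  sm_2 <- fuzzy_smooth(meta_lk_2, g2, config$w0)
  s <- ncol(sm_1)
  sv1 <- min(config$svd1 %||% min(30L, s), n1, s)
  sv2 <- min(config$svd2 %||% min(30L, s), n2, s)
  current <- batched_match(
    svd_denoise(sm_1, sv1), svd_denoise(sm_2, sv2),
    batch_size = config$batch_size, metric = config$distance_metric,
    seed = config$seed
  )
  objectives <- tibble(
    iteration = 0L, objective = attr(current, "objective")
  )

  # stage 2: iterative CCA refinement
  r_cc_eff <- min(config$r_cc, r1_eff, r2_eff)
  for (t in seq_len(config$n_iter)) {
    r_fit <- min(r_cc_eff, nrow(current) - 1L)
    cca <- cca_fit(
      scores_1[current$idx_1, , drop = FALSE],
      scores_2[current$idx_2, , drop = FALSE],
      r_cc = r_fit, ridge = config$ridge
    )
    cc_1 <- fuzzy_smooth(cc_scores(cca, scores_1, side = 1), g1, config$w1)
    cc_2 <- fuzzy_smooth(cc_scores(cca, scores_2, side = 2), g2, config$w1)
    current <- batched_match(cc_1, cc_2,
      batch_size = config$batch_size, metric = config$distance_metric,
      seed = config$seed + t
    )
    objectives <- bind_rows(objectives, tibble(
      iteration = t, objective = attr(current, "objective")
    ))
  }

  # stage 3: filter, embed, propagate, expand, score, prune
  pivots <- filter_pivots(current, config$alpha)
  emb <- final_embedding(
    all_1, all_2, meta_all_1, meta_all_2, pivots, config$r_e,
    ridge = config$ridge_final
  )
  prop <- propagate_matches(
    pivots,
    fuzzy_smooth(meta_all_1, g1, config$w0),
    fuzzy_smooth(meta_all_2, g2, config$w0),
    metric = config$distance_metric,
    percentile = config$propagation_percentile
  )
  meta_matching <- bind_rows(pivots, prop)
  sc <- expand_to_single_cells(meta_matching, map_1, map_2)
  matching <- score_and_prune(sc, emb$emb_1, emb$emb_2,
    direction = config$prune_direction
  )

  structure(
    list(
      matching = matching,
      pivots = pivots,
      metacell_matching = meta_matching,
      embeddings = list(emb$emb_1, emb$emb_2),
      cca_model = emb$model,
      objectives = objectives,
      maps = list(map_1, map_2),
      config = config,
      linkage = linked$linkage,
      cell_ids = list(dataset_1$cell_ids, dataset_2$cell_ids),
      cell_types = list(dataset_1$cell_types, dataset_2$cell_types)
    ),
    class = "maxfuse_fit"
  )
}

#' @export
print.maxfuse_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<maxfuse_fit>\n  %d x %d cells (%d x %d meta-cells)\n",
      "  %d refined pivots, %d propagated meta-cell matches\n",
      "  %d single-cell matches (prune: %s)\n",
      "  embedding dimension %d; mean match score %.3f\n"
    ),
    length(x$cell_ids[[1]]), length(x$cell_ids[[2]]),
    x$maps[[1]]$n_meta, x$maps[[2]]$n_meta,
    nrow(x$pivots), sum(x$metacell_matching$provenance == "propagated"),
    nrow(x$matching), x$config$prune_direction,
    ncol(x$embeddings[[1]]), mean(x$matching$score)
  ))
  invisible(x)
}
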