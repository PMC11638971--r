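# Tri-modal integration: two pairwise runs share the intermediary modality,
# their refined pivots are chained, and a generalized CCA on the chained
# pivots embeds all three views in one space.

pca_basis <- function(A, r) {
  A <- as.matrix(A)
  ctr <- colMeans(A)
  Ac <- sweep(A, 2L, ctr, "-")
  sv <- svd(Ac, nu = r, nv = r)
  for (j in seq_len(r)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  list(
    center = ctr, rotation = sv$v[, seq_len(r), drop = FALSE],
    scores = sv$u %*% diag(sv$d[seq_len(r)], r)
  )
}

#' Tri-modal integration through a shared intermediary modality
#'
#' Runs two pairwise integrations — modality 2 versus modality 1 and
#' modality 2 versus modality 3, with modality 2 (typically RNA) as the
#' higher-resolution intermediary on both — chains their refined pivots
#' through the shared modality-2 meta-cells into tri-modal pivots, and fits
#' a MAXVAR generalized CCA on the pivots' PCA-reduced all-feature rows to
#' produce a joint embedding of all cells in all three modalities.
#'
#' @param dataset_1,dataset_2,dataset_3 [modality_dataset()]s; `dataset_2`
#'   is the intermediary and is the side on which meta-cells are built in
#'   both pairwise runs.
#' @param linkage_12 [linkage_map()] between modalities 1 and 2.
#' @param linkage_23 [linkage_map()] between modalities 2 and 3.
#' @param config A [maxfuse_config()] applied to both pairwise runs
#'   (modality 2 takes the side-1 settings in each run, so its meta-cell
#'   partition is identical across the two).
#' @return Object of class `maxfuse_fit3`: `fits` (the two pairwise
#'   [maxfuse_fit()] objects), `triples` (chained meta-cell pivots with
#'   columns `idx_1`, `idx_2`, `idx_3`), `gcca` (the fitted
#'   [gcca_fit()] model), and `embeddings`, one matrix of gCCA scores per
#'   modality for every single cell.
#' @export
maxfuse_fit3 <- function(dataset_1, dataset_2, dataset_3,
                         linkage_12, linkage_23,
                         config = maxfuse_config()) {
  # modality 2 is side 1 of both pairwise runs
  linkage_21 <- linkage_map(linkage_12$feature_2, linkage_12$feature_1,
    transform = linkage_12$transform
  )
  fit_21 <- maxfuse_fit(dataset_2, dataset_1, linkage_21, config)
  fit_23 <- maxfuse_fit(dataset_2, dataset_3, linkage_23, config)
  if (!identical(
    fit_21$maps[[1]]$assignment,
    fit_23$maps[[1]]$assignment
  )) {
    abort("intermediary meta-cell partitions differ between pairwise runs")
  }

  # chain: (mod1, mod2) pivots then (mod2, mod3) pivots
  pivots_12 <- new_match_table(
    fit_21$pivots$idx_2, fit_21$pivots$idx_1,
    distance = fit_21$pivots$distance, provenance = "refined_pivot"
  )
  triples <- chain_pivots(pivots_12, fit_23$pivots)

  maps <- list(fit_21$maps[[2]], fit_21$maps[[1]], fit_23$maps[[2]])
  datasets <- list(dataset_1, dataset_2, dataset_3)
  r_dims <- c(config$r2, config$r1, config$r2)
  bases <- Map(function(map, rr) {
    pca_basis(
      map$all_means,
      min(rr, ncol(map$all_means), map$n_meta - 1L)
    )
  }, maps, r_dims)

  idx <- list(triples$idx_1, triples$idx_2, triples$idx_3)
  views <- Map(function(b, ix) b$scores[ix, , drop = FALSE], bases, idx)
  r_g <- min(
    config$r_e, vapply(views, ncol, integer(1)),
    nrow(triples) - 1L
  )
  if (r_g < 1L) abort("too few chained pivots for a tri-modal embedding")
  model <- gcca_fit(views, r = r_g, ridge = config$ridge)

  embeddings <- Map(function(ds, b, v) {
    sc <- sweep(zscore_cols(ds$matrix), 2L, b$center, "-") %*% b$rotation
    gcca_scores(model, sc, v)
  }, datasets, bases, seq_along(datasets))

  structure(
    list(
      fits = list(fit_21 = fit_21, fit_23 = fit_23),
      triples = triples,
      gcca = model,
      embeddings = embeddings,
      maps = maps,
      config = config
    ),
    class = "maxfuse_fit3"
  )
}

#' @export
print.maxfuse_fit3 <- function(x, ...) {
  cat(sprintf(
    "<maxfuse_fit3> %d chained tri-modal pivots; embedding dimension %d\n",
    nrow(x$triples), ncol(x$embeddings[[1]])
  ))
  invisible(x)
}
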