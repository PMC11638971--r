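# Synthetic co-assayed multiome generator: a shared latent cell state with
# cluster structure is observed through modality-specific linear feature
# maps; a controllable subset of features is linked across modalities with
# controllable cross-modal correlation, and the true cell pairing is masked
# by independent row shuffles and recorded as ground truth.

#' Generate two or three linked synthetic modalities
#'
#' Each cell i carries a latent state `L_i = mu_cluster + N(0, I)`, with
#' cluster means drawn so the between/within variance ratio equals
#' `separation`. Modality m observes `L %*% W_m + noise`. For each of the
#' `s_linked` linked feature pairs, the modality-2 column is
#' `rho * scale(signal_1) + sqrt(1 - rho^2) * independent + noise`, so the
#' expected cross-modal correlation of a linked pair is about
#' `rho * sd_signal / sd_total`. Rows are shuffled independently per
#' modality; the masked pairing is returned as ground truth for evaluation.
#'
#' @param n_cells Number of co-assayed cells.
#' @param n_clusters Number of cell-state clusters (>= 2).
#' @param latent_dim Latent dimension of the shared cell state.
#' @param p1,p2,p3 Feature counts; `p3 = NULL` generates two modalities.
#' @param s_linked Number of linked feature pairs between modalities 1 and 2
#'   (`<= min(p1, p2)`).
#' @param s_linked_23 Linked pairs between modalities 2 and 3 (tri-modal
#'   only).
#' @param rho Cross-modal correlation of the linked features, in \[0, 1\].
#' @param rho_23 Linkage strength of the 2-3 links (default `rho`).
#' @param noise_sd_1,noise_sd_2,noise_sd_3 Additive Gaussian noise SD per
#'   modality (per-feature latent signal SD is about
#'   `sqrt(separation + 1)`).
#' @param dropout_2 Probability of zeroing an entry of modality 2 (emulates
#'   panel dropout), in \[0, 1).
#' @param missing_cluster Optional `list(modality =, cluster =)`: removes
#'   one cluster's cells from one modality before shuffling, so the two
#'   modalities have mismatched populations.
#' @param separation Between/within variance ratio of the cluster means.
#' @param seed Integer seed; identical seeds give identical outputs.
#' @return A list: `mod1`, `mod2` (and `mod3`) as [modality_dataset()]s with
#'   `cell_types` set to the cluster labels; `linkage_12` (and `linkage_23`)
#'   as [linkage_map()]s; `truth` with `pairing` (tibble `idx_1`, `idx_2`
#'   (, `idx_3`) of row indices that are the same cell) and per-modality
#'   `clusters`.
#' @examples
#' sim <- simulate_modalities(n_cells = 200, seed = 1)
#' sim$mod1
#' head(sim$truth$pairing)
#' @export
simulate_modalities <- function(n_cells = 1000, n_clusters = 5,
                                latent_dim = 10,
                                p1 = 300, p2 = 60, p3 = NULL,
                                s_linked = 30, s_linked_23 = 30,
                                rho = 0.7, rho_23 = rho,
                                noise_sd_1 = 1, noise_sd_2 = 1,
                                noise_sd_3 = 1,
                                dropout_2 = 0, missing_cluster = NULL,
                                separation = 8, seed = 1) {
  n_cells <- check_count(n_cells, "n_cells", 2L)
  n_clusters <- check_count(n_clusters, "n_clusters", 2L)
  check_range(rho, "rho", 0, 1)
  check_range(dropout_2, "dropout_2", 0, 1, hi_open = TRUE)
  if (s_linked > min(p1, p2)) {
    abort("s_linked must not exceed min(p1, p2)")
  }
  tri <- !is.null(p3)
  if (tri && s_linked_23 > min(p2, p3)) {
    abort("s_linked_23 must not exceed min(p2, p3)")
  }
  set.seed(seed)

  clusters <- sort(rep_len(seq_len(n_clusters), n_cells))
  # simplex-like layout: cluster means along random orthonormal directions,
  # scaled so every pair of clusters is separated at the same
  # between/within variance ratio (requires n_clusters <= latent_dim for
  # exact orthogonality; otherwise directions are random unit vectors)
  dirs <- matrix(rnorm(latent_dim * n_clusters), latent_dim, n_clusters)
  if (n_clusters <= latent_dim) {
    dirs <- qr.Q(qr(dirs))
  } else {
    dirs <- sweep(dirs, 2L, sqrt(colSums(dirs^2)), "/")
  }
  mu <- t(dirs) * sqrt(separation * latent_dim)
  L <- mu[clusters, , drop = FALSE] +
    matrix(rnorm(n_cells * latent_dim), n_cells, latent_dim)

  feature_map <- function(p) {
    matrix(rnorm(latent_dim * p, sd = 1 / sqrt(latent_dim)), latent_dim, p)
  }
  observe <- function(p, noise_sd) {
    L %*% feature_map(p) + matrix(rnorm(n_cells * p, sd = noise_sd),
      n_cells, p
    )
  }
  # modality 1: plain linear observation; its first s_linked columns are the
  # linked signals
  W1 <- feature_map(p1)
  signal_1 <- L %*% W1
  Y <- signal_1 + matrix(rnorm(n_cells * p1, sd = noise_sd_1), n_cells, p1)

  # The linked block carries no extra observation noise: the
  # sqrt(1 - rho^2) independent component is the noise term, so the
  # realized cross-modal correlation of a linked pair tracks rho.
  linked_from <- function(signal, s, rho_use, p_other, noise_sd) {
    sig <- scale(signal[, seq_len(s), drop = FALSE]) # unit-variance signal
    indep <- matrix(rnorm(n_cells * s), n_cells, s)
    linked <- rho_use * sig + sqrt(1 - rho_use^2) * indep
    rest <- if (p_other > s) observe(p_other - s, noise_sd) else NULL
    cbind(linked, rest)
  }
  Z <- linked_from(signal_1, s_linked, rho, p2, noise_sd_2)
  if (dropout_2 > 0) {
    Z[matrix(runif(length(Z)) < dropout_2, nrow(Z), ncol(Z))] <- 0
  }

  f1 <- paste0("g", seq_len(p1))
  f2 <- paste0("pr", seq_len(p2))
  lk12 <- linkage_map(f1[seq_len(s_linked)], f2[seq_len(s_linked)])

  mats <- list(Y, Z)
  feats <- list(f1, f2)
  if (tri) {
    # modality 3 linked to modality 2 through the *latent* signal of the
    # linked block of modality 2 (columns 1..s_linked_23 of Z's signal part)
    s23 <- s_linked_23
    # modality-2's first s23 observed columns are the link source
    Zsig <- Z[, seq_len(s23), drop = FALSE]
    M3 <- linked_from(Zsig, s23, rho_23, p3, noise_sd_3)
    f3 <- paste0("pk", seq_len(p3))
    mats <- c(mats, list(M3))
    feats <- c(feats, list(f3))
  }

  # optional removal of one cluster from one modality
  keep <- lapply(mats, function(m) seq_len(n_cells))
  if (!is.null(missing_cluster)) {
    mm <- check_count(missing_cluster$modality, "missing_cluster$modality")
    cc <- check_count(missing_cluster$cluster, "missing_cluster$cluster")
    if (mm > length(mats)) abort("missing_cluster$modality out of range")
    if (cc > n_clusters) abort("missing_cluster$cluster out of range")
    if (n_clusters < 3L) {
      abort("cluster removal would leave fewer than 2 clusters")
    }
    keep[[mm]] <- which(clusters != cc)
  }

  perms <- lapply(keep, function(kk) kk[sample.int(length(kk))])
  datasets <- Map(function(m, f, pm) {
    modality_dataset(
      m[pm, , drop = FALSE],
      cell_ids = paste0("cell_", pm),
      feature_ids = f,
      cell_types = paste0("cluster_", clusters[pm])
    )
  }, mats, feats, perms)

  # truth: original cell -> row index in each shuffled modality
  pos <- lapply(perms, function(pm) {
    p <- rep(NA_integer_, n_cells)
    p[pm] <- seq_along(pm)
    p
  })
  common <- Reduce(intersect, lapply(perms, sort))
  pairing <- tibble(idx_1 = pos[[1]][common], idx_2 = pos[[2]][common])
  if (tri) pairing$idx_3 <- pos[[3]][common]

  out <- list(
    mod1 = datasets[[1]], mod2 = datasets[[2]],
    linkage_12 = lk12,
    truth = list(
      pairing = pairing,
      clusters = lapply(perms, function(pm) paste0("cluster_", clusters[pm]))
    )
  )
  if (tri) {
    out$mod3 <- datasets[[3]]
    out$linkage_23 <- linkage_map(
      feats[[2]][seq_len(s_linked_23)], feats[[3]][seq_len(s_linked_23)]
    )
  }
  out
}

#' Reduce a linked panel to its top-k features
#'
#' Emulates integration with a smaller targeted panel: keeps the `keep_k`
#' highest-ranked linked features of a modality (default ranking: variance)
#' and restricts the linkage map accordingly. Non-linked features are kept.
#'
#' @param dataset A [modality_dataset()] (the smaller-panel side).
#' @param linkage A [linkage_map()]; `side` says which of its columns refers
#'   to `dataset`.
#' @param keep_k Number of linked features to keep, `1 <= keep_k <= s`.
#' @param ranking Optional numeric vector (one value per linkage row, larger
#'   = more important); default is the feature variance in `dataset`.
#' @param side 1 or 2.
#' @return List with the reduced `dataset` and `linkage`.
#' @export
reduce_panel <- function(dataset, linkage, keep_k, ranking = NULL, side = 2) {
  s <- nrow(linkage)
  keep_k <- check_count(keep_k, "keep_k")
  if (keep_k > s) abort(sprintf("keep_k = %d exceeds s = %d", keep_k, s))
  feats <- if (side == 2) linkage$feature_2 else linkage$feature_1
  idx <- match(feats, dataset$feature_ids)
  if (anyNA(idx)) abort("linkage names features absent from the dataset")
  if (is.null(ranking)) {
    ranking <- apply(dataset$matrix[, idx, drop = FALSE], 2L, var)
  }
  if (length(ranking) != s) abort("ranking must have one value per link")
  keep_rows <- order(ranking, decreasing = TRUE)[seq_len(keep_k)]
  keep_rows <- sort(keep_rows)
  drop_feats <- feats[-keep_rows]
  keep_cols <- setdiff(dataset$feature_ids, drop_feats)
  ds <- modality_dataset(
    dataset$matrix[, keep_cols, drop = FALSE],
    cell_ids = dataset$cell_ids, feature_ids = keep_cols,
    cell_types = dataset$cell_types
  )
  lk <- linkage[keep_rows, , drop = FALSE]
  class(lk) <- unique(c("linkage_map", class(lk)))
  list(dataset = ds, linkage = lk)
}
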