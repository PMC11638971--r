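#' Pipeline configuration
#'
#' Collects and validates every tunable parameter of the matching pipeline.
#' Defaults follow the robust ranges reported for the method: smoothing
#' weights 0.7, three refinement iterations, 15-nearest-neighbor graphs,
#' meta-cells of target size 2 on the high-dimensional modality only, 30
#' principal components per modality, 20 canonical components, no pivot
#' filtering (`alpha = 0`), and propagation without a distance cut-off.
#'
#' @param w0 Smoothing weight in \[0, 1\] used for the initial linked-feature
#'   smoothing (1 = no smoothing).
#' @param w1 Smoothing weight in \[0, 1\] used on embedding coordinates during
#'   refinement.
#' @param n_iter Number of refinement iterations `T` (>= 0; 0 skips
#'   refinement and uses the initial matching).
#' @param k_nn1,k_nn2 Neighborhood sizes (including self) of the all-feature
#'   graphs, per modality.
#' @param metacell_size1,metacell_size2 Target mean meta-cell size per
#'   modality; 1 (or `"off"`) disables aggregation for that modality.
#' @param svd1,svd2 Number of singular components used to project the
#'   smoothed linked features before the initial assignment; `NULL` means
#'   `min(30, s)` where s is the number of linked features.
#' @param r1,r2 Principal components retained from each all-feature matrix.
#' @param r_cc CCA embedding dimension during refinement
#'   (`r_cc <= min(r1, r2)`).
#' @param r_e Dimension of the final joint embedding.
#' @param alpha Pivot filtering proportion in \[0, 1): the
#'   `ceiling((1 - alpha) * n_min)` closest pairs are kept as refined pivots.
#' @param propagation_percentile Percentile in (0, 100\] of nearest-pivot
#'   distances above which propagated matches are dropped; 100 keeps all.
#' @param prune_direction `"none"`, `"1_to_2"` (keep the best match for each
#'   modality-1 cell) or `"2_to_1"`.
#' @param distance_metric `"correlation"` (1 - Pearson) or `"euclidean"`,
#'   used for cross-modal distances and neighbor graphs.
#' @param ridge Ridge regularization for the refinement CCA fits (which run
#'   on low-dimensional PCA scores); `NULL` uses `1e-3 * trace(C) / dim`
#'   per side.
#' @param ridge_final Ridge for the final all-feature CCA; `NULL` uses the
#'   canonical-ridge default `trace(C) / dim` per side, since that fit has
#'   as many loadings as features and overfits under light shrinkage.
#' @param batch_size Cells per batch when the larger side is matched in
#'   random batches; `Inf` (or `"off"`) disables batching.
#' @param seed Integer seed controlling meta-cell clustering, batching and
#'   any other randomized step.
#' @return A validated list of class `maxfuse_config`.
#' @export
maxfuse_config <- function(w0 = 0.7, w1 = 0.7, n_iter = 3,
                           k_nn1 = 15, k_nn2 = 15,
                           metacell_size1 = 2, metacell_size2 = 1,
                           svd1 = NULL, svd2 = NULL,
                           r1 = 30, r2 = 30, r_cc = 20, r_e = 20,
                           alpha = 0, propagation_percentile = 100,
                           prune_direction = c("none", "1_to_2", "2_to_1"),
                           distance_metric = c("correlation", "euclidean"),
                           ridge = NULL, ridge_final = NULL,
                           batch_size = Inf, seed = 42) {
  norm_off <- function(x, name) {
    if (identical(x, "off")) {
      return(if (name == "batch_size") Inf else 1)
    }
    x
  }
  metacell_size1 <- norm_off(metacell_size1, "metacell_size1")
  metacell_size2 <- norm_off(metacell_size2, "metacell_size2")
  batch_size <- norm_off(batch_size, "batch_size")

  cfg <- list(
    w0 = check_range(w0, "w0", 0, 1),
    w1 = check_range(w1, "w1", 0, 1),
    n_iter = check_count(n_iter, "n_iter", min = 0L),
    k_nn1 = check_count(k_nn1, "k_nn1", min = 2L),
    k_nn2 = check_count(k_nn2, "k_nn2", min = 2L),
    metacell_size1 = check_range(metacell_size1, "metacell_size1", 1, Inf),
    metacell_size2 = check_range(metacell_size2, "metacell_size2", 1, Inf),
    svd1 = if (is.null(svd1)) NULL else check_count(svd1, "svd1"),
    svd2 = if (is.null(svd2)) NULL else check_count(svd2, "svd2"),
    r1 = check_count(r1, "r1"),
    r2 = check_count(r2, "r2"),
    r_cc = check_count(r_cc, "r_cc"),
    r_e = check_count(r_e, "r_e"),
    alpha = check_range(alpha, "alpha", 0, 1, hi_open = TRUE),
    propagation_percentile = check_range(
      propagation_percentile, "propagation_percentile", 0, 100,
      lo_open = FALSE
    ),
    prune_direction = match.arg(prune_direction),
    distance_metric = match.arg(distance_metric),
    ridge = if (is.null(ridge)) NULL else
      check_range(ridge, "ridge", 0, Inf),
    ridge_final = if (is.null(ridge_final)) NULL else
      check_range(ridge_final, "ridge_final", 0, Inf),
    batch_size = if (is.infinite(batch_size)) Inf else
      check_count(batch_size, "batch_size", min = 2L),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$r_cc > min(cfg$r1, cfg$r2)) {
    abort("`r_cc` must not exceed min(r1, r2)")
  }
  structure(cfg, class = "maxfuse_config")
}

#' @export
print.maxfuse_config <- function(x, ...) {
  cat("<maxfuse_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm, if (is.null(v)) "auto" else
      paste(format(v), collapse = " ")))
  }
  invisible(x)
}

#' Read / write a configuration as YAML
#'
#' The YAML round-trip is lossless: `read_config(write_config(cfg, f))`
#' reproduces `cfg` exactly. Fields omitted from the file keep their
#' defaults.
#'
#' @param path File path.
#' @param config A [maxfuse_config()].
#' @return `read_config` returns a [maxfuse_config()]; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(maxfuse_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    abort(sprintf("unknown config field(s): %s", paste(extra, collapse = ", ")))
  }
  if (!is.null(vals$batch_size) && identical(vals$batch_size, "off")) {
    vals$batch_size <- Inf
  }
  do.call(maxfuse_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "maxfuse_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (is.infinite(vals$batch_size)) vals$batch_size <- "off"
  yaml::write_yaml(vals, path)
  invisible(path)
}
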