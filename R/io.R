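# Writing and re-reading pipeline results. All indices in files are
# 0-based (documented in the headers); in-memory tables are 1-based.

#' Write integration results to a directory
#'
#' Writes `matching.tsv` (columns `idx_mod1`, `idx_mod2`, `distance`,
#' `score`, `provenance`; indices 0-based), one `embedding_mod<k>.csv` per
#' modality (cell id first column, then the `r_e` embedding coordinates),
#' a `config.yaml` snapshot, and `metrics.json` when both modalities carry
#' cell-type labels.
#'
#' @param fit A [maxfuse_fit()] result.
#' @param out_dir Output directory (created if needed).
#' @param metrics Optional precomputed one-row metric table; by default
#'   metrics are computed from the fit when labels are available.
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(fit, out_dir, metrics = NULL) {
  stopifnot(inherits(fit, "maxfuse_fit"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory %s", out_dir))
  }
  files <- character(0)

  mt <- fit$matching
  if (nrow(mt) == 0L) warn("writing an empty match table")
  path_m <- file.path(out_dir, "matching.tsv")
  write_match_table(mt, path_m)
  files <- c(files, path_m)

  for (k in 1:2) {
    emb <- fit$embeddings[[k]]
    df <- as.data.frame(emb)
    names(df) <- paste0("e", seq_len(ncol(emb)))
    df <- cbind(cell_id = fit$cell_ids[[k]], df)
    path_e <- file.path(out_dir, sprintf("embedding_mod%d.csv", k))
    readr::write_csv(df, path_e)
    files <- c(files, path_e)
  }

  path_c <- file.path(out_dir, "config.yaml")
  write_config(fit$config, path_c)
  files <- c(files, path_c)

  ct <- fit$cell_types
  if (is.null(metrics) && !is.null(ct[[1]]) && !is.null(ct[[2]]) &&
    nrow(mt) > 0L) {
    metrics <- evaluate_integration(
      mt, fit$embeddings[[1]], fit$embeddings[[2]], ct[[1]], ct[[2]]
    )
  }
  if (!is.null(metrics)) {
    path_j <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(as.list(metrics),
      path_j,
      auto_unbox = TRUE, digits = NA
    )
    files <- c(files, path_j)
  }
  invisible(files)
}

#' Write / read a match table as TSV
#'
#' On disk the indices are 0-based (`idx_mod1`, `idx_mod2`); reading
#' converts back to 1-based.
#'
#' @param match_table A `match_table`.
#' @param path File path.
#' @return `read_match_table` returns a `match_table` tibble.
#' @export
write_match_table <- function(match_table, path) {
  df <- tibble(
    idx_mod1 = match_table$idx_1 - 1L,
    idx_mod2 = match_table$idx_2 - 1L,
    distance = match_table$distance,
    score = match_table$score,
    provenance = match_table$provenance
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_match_table
#' @export
read_match_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("match table not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  new_match_table(df$idx_mod1 + 1L, df$idx_mod2 + 1L,
    distance = df$distance, score = df$score,
    provenance = df$provenance %||% "initial", level = "singlecell"
  )
}

#' Read an embedding CSV written by [write_outputs()]
#'
#' @param path File path.
#' @return A list with `cell_ids` and the numeric `embedding` matrix.
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) abort(sprintf("embedding file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  emb <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(emb) <- "double"
  list(cell_ids = as.character(df[[1]]), embedding = emb)
}
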