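# broom-style accessors and ggplot2 visualization for fitted objects.

#' Tidy the single-cell match table of a fit
#'
#' @param x A [maxfuse_fit()] object.
#' @param level `"singlecell"` (default) returns the final single-cell
#'   matching; `"metacell"` the pooled meta-cell matching.
#' @param ... Unused.
#' @return A tibble with one row per matched pair (`idx_1`, `idx_2`,
#'   `distance`, `score`, `provenance`, `level`).
#' @export
tidy.maxfuse_fit <- function(x, level = c("singlecell", "metacell"), ...) {
  level <- match.arg(level)
  out <- if (level == "singlecell") x$matching else x$metacell_matching
  tibble::as_tibble(out)
}

#' One-row summary of a fit
#'
#' @param x A [maxfuse_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble: cell counts, meta-cell counts, pivot and match
#'   counts, refinement iterations, final assignment objective, embedding
#'   dimension, leading canonical correlation and mean match score.
#' @export
glance.maxfuse_fit <- function(x, ...) {
  tibble(
    n_cells_1 = length(x$cell_ids[[1]]),
    n_cells_2 = length(x$cell_ids[[2]]),
    n_meta_1 = x$maps[[1]]$n_meta,
    n_meta_2 = x$maps[[2]]$n_meta,
    n_pivots = nrow(x$pivots),
    n_matches = nrow(x$matching),
    n_iter = x$config$n_iter,
    objective = x$objectives$objective[nrow(x$objectives)],
    r_e = ncol(x$embeddings[[1]]),
    leading_correlation = x$cca_model$correlations[1],
    mean_score = mean(x$matching$score)
  )
}

#' Tidy a CCA model
#'
#' @param x A [cca_fit()] or [gcca_fit()] object.
#' @param ... Unused.
#' @return A tibble with `component` and `correlation`.
#' @export
tidy.maxfuse_cca <- function(x, ...) {
  tibble(
    component = seq_along(x$correlations),
    correlation = x$correlations
  )
}

#' @rdname tidy.maxfuse_cca
#' @export
tidy.maxfuse_gcca <- function(x, ...) {
  tibble(
    component = seq_along(x$correlations),
    correlation = x$correlations,
    eigenvalue = x$eigenvalues
  )
}

embedding_frame <- function(embeddings, cell_types, dims) {
  purrr::imap_dfr(embeddings, function(emb, k) {
    tibble(
      modality = paste0("mod", k),
      dim1 = emb[, dims[1]],
      dim2 = emb[, dims[2]],
      cell_type = if (!is.null(cell_types[[k]])) cell_types[[k]] else
        NA_character_
    )
  })
}

#' Plot the joint embedding of a fit
#'
#' Scatter plot of two embedding coordinates for both modalities pooled,
#' colored by modality (default) or by cell type. A well-integrated result
#' mixes the modalities within each cell-type cluster.
#'
#' @param object A [maxfuse_fit()] (or `maxfuse_fit3`) object.
#' @param color `"modality"` or `"cell_type"`.
#' @param dims Length-2 integer vector of embedding coordinates to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.maxfuse_fit <- function(object, color = c("modality", "cell_type"),
                                 dims = c(1, 2), ...) {
  color <- match.arg(color)
  df <- embedding_frame(object$embeddings, object$cell_types, dims)
  ggplot2::ggplot(df, ggplot2::aes(
    .data$dim1, .data$dim2,
    color = .data[[color]]
  )) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::labs(
      x = sprintf("embedding %d", dims[1]),
      y = sprintf("embedding %d", dims[2])
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.maxfuse_fit
#' @export
autoplot.maxfuse_fit3 <- function(object, color = c("modality", "cell_type"),
                                  dims = c(1, 2), ...) {
  color <- match.arg(color)
  types <- list(NULL, NULL, NULL)
  df <- embedding_frame(object$embeddings, types, dims)
  if (color == "cell_type") color <- "modality"
  ggplot2::ggplot(df, ggplot2::aes(
    .data$dim1, .data$dim2,
    color = .data[[color]]
  )) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::theme_minimal()
}

#' Per-iteration assignment objective of a fit
#'
#' @param object A [maxfuse_fit()] object.
#' @return A ggplot of the linear-assignment objective across refinement
#'   iterations (iteration 0 is the initial linked-feature matching; the
#'   objectives of different iterations live in different embedding spaces
#'   and are comparable in trend, not in scale).
#' @export
plot_objectives <- function(object) {
  ggplot2::ggplot(
    object$objectives,
    ggplot2::aes(.data$iteration, .data$objective)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::theme_minimal()
}
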