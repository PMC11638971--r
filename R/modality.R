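#' Construct a single-modality dataset
#'
#' Bundles a cells-by-features matrix with cell and feature identifiers and,
#' optionally, per-cell type annotations. This is the basic container for one
#' modality (e.g. the RNA expression matrix, or the protein panel of a
#' multiplexed imaging run).
#'
#' @param matrix Numeric matrix, cells in rows, features in columns.
#' @param cell_ids Character vector of row identifiers (default: rownames or
#'   `cell_1 ... cell_N`).
#' @param feature_ids Character vector of column identifiers (default:
#'   colnames). Must be unique.
#' @param cell_types Optional character vector of per-cell annotations, same
#'   length as `cell_ids`.
#' @return An object of class `modality_dataset`: a list with elements
#'   `matrix`, `cell_ids`, `feature_ids`, `cell_types`.
#' @examples
#' m <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
#' ds <- modality_dataset(m)
#' dim(ds$matrix)
#' @export
modality_dataset <- function(matrix, cell_ids = NULL, feature_ids = NULL,
                             cell_types = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  cell_ids <- cell_ids %||% rownames(matrix) %||%
    paste0("cell_", seq_len(nrow(matrix)))
  feature_ids <- feature_ids %||% colnames(matrix) %||%
    paste0("feature_", seq_len(ncol(matrix)))
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  if (nrow(matrix) != length(cell_ids)) {
    abort(sprintf(
      "matrix has %d rows but %d cell ids were given",
      nrow(matrix), length(cell_ids)
    ))
  }
  if (ncol(matrix) != length(feature_ids)) {
    abort(sprintf(
      "matrix has %d columns but %d feature ids were given",
      ncol(matrix), length(feature_ids)
    ))
  }
  if (anyDuplicated(feature_ids)) {
    abort("feature ids must be unique")
  }
  bad <- which(!is.finite(matrix))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(matrix)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(matrix)) + 1L
    abort(sprintf(
      "non-finite value at cell '%s', feature '%s' (%d entries affected)",
      cell_ids[i], feature_ids[j], length(bad)
    ))
  }
  if (!is.null(cell_types)) {
    cell_types <- as.character(cell_types)
    if (length(cell_types) != length(cell_ids)) {
      abort("cell_types must have one entry per cell")
    }
  }
  dimnames(matrix) <- list(cell_ids, feature_ids)
  structure(
    list(
      matrix = matrix, cell_ids = cell_ids, feature_ids = feature_ids,
      cell_types = cell_types
    ),
    class = "modality_dataset"
  )
}

#' @export
print.modality_dataset <- function(x, ...) {
  cat(sprintf(
    "<modality_dataset> %d cells x %d features%s\n",
    length(x$cell_ids), length(x$feature_ids),
    if (is.null(x$cell_types)) "" else
      sprintf(" (%d cell types)", length(unique(x$cell_types)))
  ))
  invisible(x)
}

#' @export
dim.modality_dataset <- function(x) dim(x$matrix)

#' Read one modality from disk
#'
#' Accepts either a dense delimited matrix (cells x features with a header
#' row of feature ids, comma- or tab-separated) or a MatrixMarket sparse
#' triplet (`.mtx`) accompanied by feature and cell label files (one id per
#' line). A `celltypes` file, if given, holds one annotation per cell.
#'
#' @param path_matrix Path to the matrix (`.csv`/`.tsv`/`.txt` dense, or
#'   `.mtx` sparse).
#' @param path_features,path_cells Label files; required for `.mtx` input,
#'   optional for dense input (dense default: header/`cell_<i>`).
#' @param path_celltypes Optional path to a one-column cell annotation file.
#' @param transpose If `TRUE` the file is features x cells and is transposed
#'   after reading.
#' @return A [modality_dataset()].
#' @export
read_modality <- function(path_matrix, path_features = NULL,
                          path_cells = NULL, path_celltypes = NULL,
                          transpose = FALSE) {
  if (!file.exists(path_matrix)) {
    abort(sprintf("matrix file not found: %s", path_matrix))
  }
  if (grepl("\\.mtx$", path_matrix, ignore.case = TRUE)) {
    if (is.null(path_features) || is.null(path_cells)) {
      abort("MatrixMarket input requires feature and cell label files")
    }
    m <- as.matrix(Matrix::readMM(path_matrix))
    features <- readr::read_lines(path_features)
    cells <- readr::read_lines(path_cells)
    if (transpose) m <- t(m)
    if (nrow(m) != length(cells)) {
      abort(sprintf(
        "cell label file %s has %d ids but matrix has %d rows",
        path_cells, length(cells), nrow(m)
      ))
    }
    if (ncol(m) != length(features)) {
      abort(sprintf(
        "feature label file %s has %d ids but matrix has %d columns",
        path_features, length(features), ncol(m)
      ))
    }
  } else {
    delim <- if (grepl("\\.csv$", path_matrix, ignore.case = TRUE)) "," else "\t"
    df <- readr::read_delim(
      path_matrix,
      delim = delim, show_col_types = FALSE, progress = FALSE
    )
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    features <- colnames(df)
    if (transpose) {
      cells <- features
      features <- NULL
      m <- t(m)
    }
    if (!is.null(path_features)) {
      features <- readr::read_lines(path_features)
      if (length(features) != ncol(m)) {
        abort(sprintf(
          "feature label file %s has %d ids but matrix has %d columns",
          path_features, length(features), ncol(m)
        ))
      }
    }
    cells <- if (!is.null(path_cells)) readr::read_lines(path_cells) else
      paste0("cell_", seq_len(nrow(m)))
    if (length(cells) != nrow(m)) {
      abort(sprintf(
        "cell label file %s has %d ids but matrix has %d rows",
        path_cells, length(cells), nrow(m)
      ))
    }
  }
  cell_types <- NULL
  if (!is.null(path_celltypes)) {
    cell_types <- readr::read_lines(path_celltypes)
    if (length(cell_types) != nrow(m)) {
      abort(sprintf(
        "cell type file %s has %d entries but matrix has %d rows",
        path_celltypes, length(cell_types), nrow(m)
      ))
    }
  }
  rownames(m) <- NULL
  colnames(m) <- NULL
  modality_dataset(m, cells, features, cell_types)
}

#' Normalize a modality
#'
#' @param dataset A [modality_dataset()].
#' @param scheme One of `"none"`, `"log1p_total_scaled"` (library-size scale
#'   rows to the median total, then `log1p`), `"zscore_per_feature"`
#'   (population-SD z-score per column; constant features map to zeros), or
#'   `"log1p_then_zscore"`.
#' @return A transformed [modality_dataset()].
#' @export
normalize_modality <- function(dataset,
                               scheme = c(
                                 "none", "log1p_total_scaled",
                                 "zscore_per_feature", "log1p_then_zscore"
                               )) {
  if (!inherits(dataset, "modality_dataset")) {
    abort("`dataset` must be a modality_dataset")
  }
  scheme <- tryCatch(match.arg(scheme), error = function(e) {
    abort(sprintf("unknown normalization scheme '%s'", scheme[1]))
  })
  m <- dataset$matrix
  log1p_total <- function(m) {
    tot <- rowSums(m)
    tot[tot == 0] <- 1
    log1p(m / tot * stats::median(tot))
  }
  m <- switch(scheme,
    none = m,
    log1p_total_scaled = log1p_total(m),
    zscore_per_feature = zscore_cols(m),
    log1p_then_zscore = zscore_cols(log1p_total(m))
  )
  modality_dataset(m, dataset$cell_ids, dataset$feature_ids, dataset$cell_types)
}
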