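#' Construct a feature-linkage map
#'
#' A linkage map lists the features measured in (or predictable from) both
#' modalities — e.g. a protein and its coding gene. The linked-feature
#' matrices extracted with [make_linked_matrices()] have column j taken from
#' `feature_1[j]` on side 1 and `feature_2[j]` on side 2.
#'
#' @param feature_1,feature_2 Character vectors of equal length naming the
#'   linked features in modality 1 and modality 2.
#' @param transform Optional per-pair tag, `"identity"` (the raw feature) or
#'   `"precomputed-prediction"` (the named column already holds a cross-modal
#'   prediction). Recycled if length 1.
#' @return A tibble of class `linkage_map` with columns `feature_1`,
#'   `feature_2`, `transform`.
#' @export
linkage_map <- function(feature_1, feature_2, transform = "identity") {
  if (length(feature_1) != length(feature_2)) {
    abort("feature_1 and feature_2 must have equal length")
  }
  if (length(feature_1) == 0L) {
    abort("no linked features")
  }
  transform <- rep_len(as.character(transform), length(feature_1))
  bad <- setdiff(unique(transform), c("identity", "precomputed-prediction"))
  if (length(bad)) {
    abort(sprintf("unknown linkage transform tag '%s'", bad[1]))
  }
  out <- tibble(
    feature_1 = as.character(feature_1),
    feature_2 = as.character(feature_2),
    transform = transform
  )
  out <- distinct(out, .data$feature_1, .data$feature_2, .keep_all = TRUE)
  class(out) <- c("linkage_map", class(out))
  out
}

#' Read a feature-link table and validate it against two modalities
#'
#' The file is a two- or three-column TSV: feature id in modality 1, feature
#' id in modality 2, and optionally a transform tag. Pairs referencing a
#' feature absent from either modality are dropped with a message; if no
#' pair survives, this is a fatal error.
#'
#' @param path Path to the TSV (no header by default; a header line whose
#'   first field is not a feature of modality 1 is skipped automatically).
#' @param dataset_1,dataset_2 The two [modality_dataset()]s.
#' @return A validated [linkage_map()].
#' @export
read_linkage <- function(path, dataset_1, dataset_2) {
  if (!file.exists(path)) abort(sprintf("link table not found: %s", path))
  df <- utils::read.table(path,
    sep = "\t", header = FALSE,
    stringsAsFactors = FALSE, comment.char = ""
  )
  if (ncol(df) < 2L) abort("link table must have at least two columns")
  # tolerate a header row
  if (!df[[1]][1] %in% dataset_1$feature_ids &&
    nrow(df) > 1L && df[[1]][2] %in% dataset_1$feature_ids) {
    df <- df[-1L, , drop = FALSE]
  }
  lm <- linkage_map(df[[1]], df[[2]],
    transform = if (ncol(df) >= 3L) df[[3]] else "identity"
  )
  validate_linkage(lm, dataset_1, dataset_2)
}

validate_linkage <- function(linkage, dataset_1, dataset_2) {
  keep <- linkage$feature_1 %in% dataset_1$feature_ids &
    linkage$feature_2 %in% dataset_2$feature_ids
  if (any(!keep)) {
    message(sprintf(
      "dropping %d link(s) with features absent from a modality",
      sum(!keep)
    ))
  }
  out <- linkage[keep, , drop = FALSE]
  if (nrow(out) == 0L) abort("no linked features")
  out
}

#' Materialize the linked-feature matrices
#'
#' Extracts the columns named in the linkage map from each modality, in the
#' same order on both sides, so that column j of the two outputs corresponds
#' to the same linked feature.
#'
#' @param dataset_1,dataset_2 The two [modality_dataset()]s.
#' @param linkage A [linkage_map()].
#' @return A list with matrices `linked_1` (N1 x s) and `linked_2` (N2 x s),
#'   columns labelled `feature_1|feature_2`.
#' @export
make_linked_matrices <- function(dataset_1, dataset_2, linkage) {
  linkage <- validate_linkage(linkage, dataset_1, dataset_2)
  i1 <- match(linkage$feature_1, dataset_1$feature_ids)
  i2 <- match(linkage$feature_2, dataset_2$feature_ids)
  l1 <- dataset_1$matrix[, i1, drop = FALSE]
  l2 <- dataset_2$matrix[, i2, drop = FALSE]
  labels <- paste(linkage$feature_1, linkage$feature_2, sep = "|")
  colnames(l1) <- labels
  colnames(l2) <- labels
  list(linked_1 = l1, linked_2 = l2, linkage = linkage)
}
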