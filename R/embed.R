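# PCA reduction, (regularized) canonical correlation analysis, and MAXVAR
# generalized CCA for tri-modal pivots.

#' PCA scores of an all-feature matrix
#'
#' Column-centers the matrix and returns the first `r` principal-component
#' scores, with the same deterministic sign convention as [svd_project()].
#'
#' @param matrix Numeric matrix (cells x features).
#' @param r Number of components, `1 <= r <= min(n - 1, p)`.
#' @return n x r score matrix.
#' @export
pca_reduce <- function(matrix, r) {
  matrix <- as.matrix(matrix)
  r <- check_count(r, "r")
  r_max <- min(nrow(matrix) - 1L, ncol(matrix))
  if (r > r_max) {
    abort(sprintf("r = %d exceeds min(n - 1, p) = %d", r, r_max))
  }
  svd_project(matrix, r)
}

inv_sqrt_sym <- function(C, ridge, side, ridge_scale = 1e-3) {
  p <- ncol(C)
  lambda <- ridge %||% (ridge_scale * sum(diag(C)) / p)
  Cr <- C + diag(lambda, p)
  e <- eigen(Cr, symmetric = TRUE)
  tol <- max(e$values) * 1e-12
  if (any(e$values < tol)) {
    abort(sprintf(
      "covariance on side %s is numerically singular; supply ridge > 0",
      side
    ))
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Fit canonical correlation analysis on matched pairs
#'
#' Computes the leading `r_cc` pairs of canonical loading vectors of two
#' row-aligned matrices, with optional ridge regularization of the
#' within-view covariances (`C + lambda I`). With `ridge = 0` this is
#' classical CCA; the default `lambda = 1e-3 * trace(C)/dim` per side keeps
#' the fit stable when the number of pairs approaches the feature count.
#'
#' @param x,z Row-aligned numeric matrices (`n` matched pairs each).
#' @param r_cc Number of canonical components,
#'   `r_cc <= min(ncol(x), ncol(z), n - 1)`.
#' @param ridge Non-negative ridge penalty; `NULL` for the trace-scaled
#'   default above.
#' @param ridge_scale Multiplier of `trace(C)/dim` used when `ridge` is
#'   `NULL`. The default `1e-3` barely perturbs a well-conditioned fit;
#'   `1` gives canonical-ridge-level shrinkage appropriate when the feature
#'   count approaches the number of pairs.
#' @return Object of class `maxfuse_cca`: list with `loadings_1`
#'   (`ncol(x) x r_cc`), `loadings_2`, `correlations` (nonincreasing, in
#'   \[0, 1\]), and the centering vectors `center_1`, `center_2`.
#' @export
cca_fit <- function(x, z, r_cc, ridge = NULL, ridge_scale = 1e-3) {
  x <- as.matrix(x)
  z <- as.matrix(z)
  n <- nrow(x)
  if (nrow(z) != n) abort("x and z must have the same number of rows")
  if (n < 3L) abort("CCA requires at least 3 matched pairs")
  r_cc <- check_count(r_cc, "r_cc")
  r_max <- min(ncol(x), ncol(z), n - 1L)
  if (r_cc > r_max) {
    abort(sprintf("r_cc = %d exceeds min(p1, p2, n - 1) = %d", r_cc, r_max))
  }
  c1 <- colMeans(x)
  c2 <- colMeans(z)
  xc <- sweep(x, 2L, c1, "-")
  zc <- sweep(z, 2L, c2, "-")
  Cxx <- crossprod(xc) / n
  Czz <- crossprod(zc) / n
  Cxz <- crossprod(xc, zc) / n
  Wx <- inv_sqrt_sym(Cxx, ridge, "1", ridge_scale)
  Wz <- inv_sqrt_sym(Czz, ridge, "2", ridge_scale)
  sv <- svd(Wx %*% Cxz %*% Wz, nu = r_cc, nv = r_cc)
  A <- Wx %*% sv$u
  B <- Wz %*% sv$v
  for (j in seq_len(r_cc)) {
    if (A[which.max(abs(A[, j])), j] < 0) {
      A[, j] <- -A[, j]
      B[, j] <- -B[, j]
    }
  }
  structure(
    list(
      loadings_1 = A, loadings_2 = B,
      correlations = pmin(pmax(sv$d[seq_len(r_cc)], 0), 1),
      center_1 = c1, center_2 = c2, ridge = ridge
    ),
    class = "maxfuse_cca"
  )
}

#' @export
print.maxfuse_cca <- function(x, ...) {
  cat(sprintf(
    "<maxfuse_cca> %d components; leading correlations: %s\n",
    length(x$correlations),
    paste(round(head(x$correlations, 5), 3), collapse = ", ")
  ))
  invisible(x)
}

#' Canonical-correlation scores for all cells
#'
#' Applies the loadings of a fitted CCA model to a full matrix (including
#' cells that were not part of any matched pair), after subtracting the
#' centering vector learned at fit time.
#'
#' @param model A [cca_fit()] result.
#' @param matrix Matrix whose columns match the chosen side of the model.
#' @param side `1` or `2`: which modality's loadings to apply.
#' @return n x r_cc score matrix.
#' @export
cc_scores <- function(model, matrix, side = 1) {
  stopifnot(inherits(model, "maxfuse_cca"))
  side <- as.character(side)
  if (!side %in% c("1", "2")) abort("side must be 1 or 2")
  L <- if (side == "1") model$loadings_1 else model$loadings_2
  ctr <- if (side == "1") model$center_1 else model$center_2
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != nrow(L)) {
    abort(sprintf(
      "matrix has %d columns but model side %s expects %d",
      ncol(matrix), side, nrow(L)
    ))
  }
  sweep(matrix, 2L, ctr, "-") %*% L
}

#' MAXVAR generalized CCA over three (or more) row-aligned views
#'
#' Extends CCA to several views: finds one loading vector per view per
#' component so that the projected variables are maximally mutually
#' correlated, via the classical MAXVAR formulation — the leading
#' eigenvectors of the sum of the views' (ridge-regularized) projection
#' operators. With two views this reduces to classical CCA.
#'
#' @param views List of >= 2 numeric matrices with the same row count
#'   (rows aligned across views, e.g. chained pivots).
#' @param r Number of components, at most the smallest view dimension.
#' @param ridge Non-negative ridge added to each view's Gram matrix (scaled
#'   as in [cca_fit()]); `NULL` for the trace-scaled default. If a view is
#'   rank-deficient at `ridge = 0`, the default ridge is applied with a
#'   warning.
#' @return Object of class `maxfuse_gcca`: `loadings` (list of p_i x r
#'   matrices, projections scaled to unit variance), `centers`,
#'   `eigenvalues` of the MAXVAR operator, and `correlations`, the mean
#'   pairwise Pearson correlation of the projected views per component.
#' @export
gcca_fit <- function(views, r, ridge = NULL) {
  if (!is.list(views) || length(views) < 2L) {
    abort("`views` must be a list of at least two matrices")
  }
  views <- lapply(views, as.matrix)
  n <- nrow(views[[1]])
  if (!all(vapply(views, nrow, integer(1)) == n)) {
    abort("all views must have the same number of rows")
  }
  r <- check_count(r, "r")
  r_max <- min(vapply(views, ncol, integer(1)), n - 1L)
  if (r > r_max) {
    abort(sprintf("r = %d exceeds the smallest feasible dimension %d", r, r_max))
  }
  centers <- lapply(views, colMeans)
  Xc <- Map(function(v, ctr) sweep(v, 2L, ctr, "-"), views, centers)
  grams <- lapply(Xc, crossprod)
  lam <- Map(function(G, X) {
    l <- ridge %||% (1e-3 * sum(diag(G)) / ncol(G) / nrow(X))
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    if (l == 0 && min(ev) < max(ev) * 1e-10) {
      warn("rank-deficient view at ridge = 0; falling back to default ridge")
      l <- 1e-3 * sum(diag(G)) / ncol(G) / nrow(X)
    }
    l
  }, grams, Xc)
  Ginv <- Map(function(G, l) solve(G + diag(nrow(G) * l, ncol(G))), grams, lam)
  M <- matrix(0, n, n)
  for (i in seq_along(Xc)) {
    M <- M + Xc[[i]] %*% Ginv[[i]] %*% t(Xc[[i]])
  }
  e <- eigen(M, symmetric = TRUE)
  g <- e$vectors[, seq_len(r), drop = FALSE]
  loadings <- Map(function(X, Gi) Gi %*% crossprod(X, g), Xc, Ginv)
  # unit-variance projections, sign anchored on view 1
  for (j in seq_len(r)) {
    a1 <- loadings[[1]][, j]
    if (a1[which.max(abs(a1))] < 0) {
      for (i in seq_along(loadings)) loadings[[i]][, j] <- -loadings[[i]][, j]
    }
  }
  loadings <- Map(function(X, L) {
    proj <- X %*% L
    s <- sqrt(colMeans(proj^2))
    s[s == 0] <- 1
    sweep(L, 2L, s, "/")
  }, Xc, loadings)
  projs <- Map(`%*%`, Xc, loadings)
  npair <- 0L
  corsum <- numeric(r)
  for (i in seq_along(projs)) {
    for (k in seq_along(projs)) {
      if (k > i) {
        corsum <- corsum + vapply(
          seq_len(r),
          function(j) stats::cor(projs[[i]][, j], projs[[k]][, j]),
          numeric(1)
        )
        npair <- npair + 1L
      }
    }
  }
  structure(
    list(
      loadings = loadings, centers = centers,
      eigenvalues = e$values[seq_len(r)],
      correlations = corsum / npair
    ),
    class = "maxfuse_gcca"
  )
}

#' @export
print.maxfuse_gcca <- function(x, ...) {
  cat(sprintf(
    "<maxfuse_gcca> %d views, %d components; mean pairwise correlations: %s\n",
    length(x$loadings), length(x$correlations),
    paste(round(head(x$correlations, 5), 3), collapse = ", ")
  ))
  invisible(x)
}

#' Scores of one view under a fitted gCCA model
#'
#' @param model A [gcca_fit()] result.
#' @param matrix Matrix with the feature count of the chosen view.
#' @param view View index (1-based).
#' @return n x r score matrix.
#' @export
gcca_scores <- function(model, matrix, view) {
  stopifnot(inherits(model, "maxfuse_gcca"))
  view <- check_count(view, "view")
  if (view > length(model$loadings)) abort("no such view")
  L <- model$loadings[[view]]
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != nrow(L)) {
    abort(sprintf(
      "matrix has %d columns but view %d expects %d",
      ncol(matrix), view, nrow(L)
    ))
  }
  sweep(matrix, 2L, model$centers[[view]], "-") %*% L
}
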