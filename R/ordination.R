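#' Principal component analysis of a trait table
#'
#' Reduces the traits to `k` components.  By default the analysis is run on
#' the correlation matrix (traits standardized to zero mean and unit
#' variance), appropriate when traits differ in scale by an order of
#' magnitude, and loadings are stored as eigenvector times the square root
#' of the eigenvalue so that each entry is the correlation between a trait
#' and a component.  Scores are the standardized data projected onto the
#' eigenvectors.  Components are ordered by decreasing eigenvalue, and each
#' loading column is signed so that its largest-magnitude entry is positive,
#' making loadings tables reproducible across linear-algebra backends.
#'
#' @param x a `trait_table`, or a numeric matrix / data.frame of trait
#'   columns (any number of traits; the six-trait schema applies only to
#'   `trait_table` input).
#' @param k number of components to retain (1 to the number of traits).
#' @param pca_matrix `"correlation"` (standardize first; default) or
#'   `"covariance"` (center only).
#' @return an `ordination` object: `center`, `scale`, `loadings` (traits by
#'   components), `scores` (individuals by components), `variance_explained`
#'   (percent per retained component, pre-rotation), `total_variance_explained`,
#'   `eigenvalues`, `rotation_matrix` (identity until [varimax_rotate()]),
#'   `rotated` flag, `k`, and `pca_matrix`.
#' @examples
#' tab <- generate_traits(default_design())
#' ord <- fit_pca(tab, k = 4)
#' round(ord$variance_explained, 2)
#' @export
fit_pca <- function(x, k = 4L, pca_matrix = c("correlation", "covariance")) {
  pca_matrix <- match.arg(pca_matrix)
  mat <- trait_matrix(x)
  n <- nrow(mat)
  p <- ncol(mat)
  k <- as.integer(k)
  if (n < 2L) stop("degenerate input: need at least 2 individuals for ordination")
  if (k < 1L || k > p) stop(sprintf("k must be between 1 and %d", p))
  if (n < k + 1L) stop(sprintf("need at least k + 1 = %d individuals, got %d", k + 1L, n))

  ctr <- colMeans(mat)
  sds <- apply(mat, 2L, stats::sd)
  zero_var <- colnames(mat)[sds <= .Machine$double.eps * max(abs(mat), 1)]
  if (length(zero_var) > 0L) {
    stop(sprintf("zero-variance trait(s): %s", paste(zero_var, collapse = ", ")))
  }
  scl <- if (pca_matrix == "correlation") sds else rep(1, p)
  xs <- sweep(sweep(mat, 2L, ctr), 2L, scl, "/")

  eg <- eigen(stats::cov(xs), symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  vectors <- eg$vectors
  total_var <- if (pca_matrix == "correlation") p else sum(lambda)
  var_expl_all <- 100 * lambda / total_var

  vk <- vectors[, seq_len(k), drop = FALSE]
  loadings <- vk %*% diag(sqrt(lambda[seq_len(k)]), k)
  scores <- xs %*% vk

  ## sign convention: largest-magnitude loading per column is positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
      vk[, j] <- -vk[, j]
    }
  }
  dimnames(loadings) <- list(colnames(mat), paste0("PC", seq_len(k)))
  colnames(scores) <- paste0("PC", seq_len(k))

  structure(list(
    center = ctr, scale = scl,
    loadings = loadings,
    scores = scores,
    variance_explained = var_expl_all[seq_len(k)],
    total_variance_explained = sum(var_expl_all[seq_len(k)]),
    variance_explained_all = var_expl_all,
    variance_explained_rotated = NULL,
    eigenvalues = lambda,
    eigenvectors = vk,
    rotation_matrix = diag(k),
    rotated = FALSE,
    k = k,
    n = n,
    pca_matrix = pca_matrix,
    traits = colnames(mat)
  ), class = "ordination")
}

#' Varimax rotation of retained components
#'
#' Orthogonally rotates the retained loadings to maximize the varimax
#' criterion (the sum over components of the variance of squared loadings),
#' yielding "simple structure" for interpretation.  Raw varimax (no Kaiser
#' row normalization) is the default.  Scores are rotated by the same
#' orthogonal matrix, so per-trait communalities and the total retained
#' variance are unchanged; the per-component variance is redistributed and
#' is reported separately (`variance_explained_rotated`) from the
#' pre-rotation shares.  Components are re-ordered by decreasing
#' post-rotation variance and re-signed under the same convention as
#' [fit_pca()].
#'
#' @param ord an `ordination` from [fit_pca()].
#' @param normalize use Kaiser row normalization (default `FALSE`).
#' @return the rotated `ordination`.
#' @export
varimax_rotate <- function(ord, normalize = FALSE) {
  stopifnot(inherits(ord, "ordination"))
  if (ord$k < 2L) {
    warning("varimax rotation needs at least 2 components; returning input unchanged")
    return(ord)
  }
  rot <- stats::varimax(ord$loadings, normalize = normalize, eps = 1e-10)
  loadings <- ord$loadings %*% rot$rotmat
  scores <- ord$scores %*% rot$rotmat
  rotmat <- rot$rotmat

  ## order components by decreasing rotated variance share
  share <- colSums(loadings^2)
  ord_idx <- order(share, decreasing = TRUE)
  loadings <- loadings[, ord_idx, drop = FALSE]
  scores <- scores[, ord_idx, drop = FALSE]
  rotmat <- rotmat[, ord_idx, drop = FALSE]
  for (j in seq_len(ncol(loadings))) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
      rotmat[, j] <- -rotmat[, j]
    }
  }
  dimnames(loadings) <- list(ord$traits, paste0("PC", seq_len(ord$k)))
  colnames(scores) <- paste0("PC", seq_len(ord$k))

  total_var <- if (ord$pca_matrix == "correlation") length(ord$traits) else sum(ord$eigenvalues)
  out <- ord
  out$loadings <- loadings
  out$scores <- scores
  out$rotation_matrix <- rotmat
  out$rotated <- TRUE
  out$variance_explained_rotated <- 100 * colSums(loadings^2) / total_var
  out
}

#' Varimax simplicity criterion of a loadings matrix
#'
#' Sum over components of the variance of the squared loadings; the quantity
#' [varimax_rotate()] maximizes over orthogonal rotations.
#'
#' @param loadings numeric matrix (traits by components).
#' @return scalar criterion value.
#' @export
varimax_criterion <- function(loadings) {
  sq <- loadings^2
  sum(apply(sq, 2L, function(col) mean((col - mean(col))^2)))
}

#' Project new trait data into an ordination
#'
#' @param object an `ordination`.
#' @param newdata trait table or matrix with the same traits.
#' @param ... unused.
#' @return matrix of component scores (rotated if the ordination is).
#' @export
predict.ordination <- function(object, newdata, ...) {
  mat <- trait_matrix(newdata)
  if (ncol(mat) != length(object$traits)) {
    stop(sprintf("newdata has %d traits; ordination was fitted with %d",
                 ncol(mat), length(object$traits)))
  }
  xs <- sweep(sweep(mat, 2L, object$center), 2L, object$scale, "/")
  scores <- xs %*% object$eigenvectors %*% object$rotation_matrix
  colnames(scores) <- paste0("PC", seq_len(object$k))
  scores
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d traits -> %d components (%s)\n",
              if (x$rotated) "Varimax-rotated" else "Unrotated",
              length(x$traits), x$k, x$pca_matrix))
  cat(sprintf("  variance explained (pre-rotation): %s | total %.2f%%\n",
              paste(sprintf("%.2f%%", x$variance_explained), collapse = " "),
              x$total_variance_explained))
  if (!is.null(x$variance_explained_rotated)) {
    cat(sprintf("  variance by rotated component:     %s\n",
                paste(sprintf("%.2f%%", x$variance_explained_rotated), collapse = " ")))
  }
  cat("  loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

## Extract the numeric trait matrix from trait_table / data.frame / matrix input
trait_matrix <- function(x) {
  if (inherits(x, "trait_table")) {
    mat <- as.matrix(as.data.frame(x)[, trait_names()])
  } else if (is.data.frame(x)) {
    mat <- as.matrix(x[, vapply(x, is.numeric, logical(1)), drop = FALSE])
  } else {
    mat <- as.matrix(x)
  }
  storage.mode(mat) <- "double"
  if (is.null(colnames(mat))) colnames(mat) <- paste0("trait_", seq_len(ncol(mat)))
  mat
}
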