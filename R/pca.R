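#' Principal component analysis of spectra
#'
#' Mean-centered (no variance scaling) PCA via the singular value
#' decomposition ([stats::prcomp()]), with a fixed sign convention: in every
#' loading vector the element of largest magnitude is made positive. The
#' decomposition searches for the orthonormal directions of maximal
#' variance; fluorescence intensities share units, so no autoscaling is
#' applied.
#'
#' @param X Observations x features numeric matrix.
#' @param n_components Number of components to keep; must satisfy
#'   `n_components <= min(nrow(X) - 1, ncol(X))`.
#' @return Object of class `pca_model`: list with `mean_vector`, `loadings`
#'   (features x n_components, orthonormal columns), `n_components` and
#'   `explained_variance` (non-increasing).
#' @export
fit_pca <- function(X, n_components) {
  X <- as.matrix(X)
  max_rank <- min(nrow(X) - 1L, ncol(X))
  if (n_components < 1 || n_components > max_rank) {
    stop(sprintf(
      "n_components must be in 1..%d for a %d x %d matrix",
      max_rank, nrow(X), ncol(X)
    ))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-magnitude element of each loading positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  structure(
    list(
      mean_vector = pc$center,
      loadings = loadings,
      n_components = n_components,
      explained_variance = pc$sdev[seq_len(n_components)]^2
    ),
    class = "pca_model"
  )
}

#' Project observations onto a fitted PCA model
#'
#' @param model A [fit_pca()] model.
#' @param X Observations x features matrix on the training feature space.
#' @return Observations x n_components score matrix.
#' @export
project_pca <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean_vector)) {
    stop("feature dimension does not match the fitted PCA model")
  }
  sweep(X, 2, model$mean_vector, "-") %*% model$loadings
}
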