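#' Fit a zero-mean unit-variance scaler on training features
#'
#' Standardization parameters (per-feature mean and population SD) are
#' computed from the training rows only; constant features (SD = 0) are
#' dropped and the same drop is applied at transform time, so fitting on
#' train data and transforming held-out data leaks nothing.
#'
#' @param x Numeric matrix or data frame of training features
#'   (rows = samples). At least 2 rows.
#' @return A `raman_scaler` object.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("Need at least 2 training rows to fit a scaler.",
                         class = "ramancell_scaler_error")
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))
  keep <- sdv > 0
  structure(list(mean = mu, sd = sdv, keep = keep,
                 n_dropped = sum(!keep)),
            class = "raman_scaler")
}

#' Apply a fitted scaler
#' @param scaler A `raman_scaler` from [fit_scaler()].
#' @param x Feature matrix with the same columns as the training data.
#' @return Standardized matrix (constant training features dropped).
#' @export
apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(scaler$mean))
  k <- scaler$keep
  sweep(sweep(x[, k, drop = FALSE], 2, scaler$mean[k]), 2, scaler$sd[k], `/`)
}

#' Principal component reduction fitted on training features
#'
#' Centers the training matrix on its own means and projects onto the top
#' eigenvectors of the training covariance. Held-out data must be
#' transformed with [apply_pca()], which reuses the training means and
#' loadings only.
#'
#' @param x Training feature matrix (typically already standardized).
#' @param n_components Number of components to retain (default 20).
#' @return A `raman_pca` object with orthonormal `rotation`, training
#'   `center`, per-component `variance_ratio` and `sdev`.
#' @export
fit_spectra_pca <- function(x, n_components = 20L) {
  x <- as.matrix(x)
  n_components <- as.integer(n_components)
  if (n_components < 1 || n_components > min(nrow(x) - 1L, ncol(x))) {
    abort("`n_components` must be in 1..min(rows - 1, features).",
          class = "ramancell_pca_error")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
                 center = pc$center,
                 sdev = pc$sdev[seq_len(n_components)],
                 variance_ratio = evr[seq_len(n_components)],
                 total_components = length(pc$sdev),
                 n_components = n_components),
            class = "raman_pca")
}

#' Project features onto fitted principal components
#' @param pca A `raman_pca` from [fit_spectra_pca()].
#' @param x Feature matrix (same columns as the training data).
#' @return Score matrix, `n_components` columns.
#' @export
apply_pca <- function(pca, x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(pca$center))
  sweep(x, 2, pca$center) %*% pca$rotation
}

#' @export
tidy.raman_pca <- function(x, ...) {
  tibble(component = seq_len(x$n_components),
         sdev = x$sdev,
         variance_ratio = x$variance_ratio,
         cumulative = cumsum(x$variance_ratio))
}

#' @export
glance.raman_pca <- function(x, ...) {
  tibble(n_components = x$n_components,
         variance_retained = sum(x$variance_ratio))
}

#' @export
print.raman_pca <- function(x, ...) {
  cat(sprintf("PCA: %d components, %.2f%% of training variance retained\n",
              x$n_components, 100 * sum(x$variance_ratio)))
  invisible(x)
}
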