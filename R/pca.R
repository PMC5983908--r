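#' Fit RNFL eigen-features by principal component analysis
#'
#' Learns the top-`K` orthonormal spatial modes of variation
#' (eigen-images) of a stack of standardized thickness maps. Because the
#' number of pixels far exceeds the number of scans, the eigenvectors of
#' the pixel covariance are computed through the Gram (duality) trick:
#' the `n x n` matrix of scan inner products is eigendecomposed and its
#' eigenvectors mapped back to pixel space. The solver is deterministic;
#' component signs are canonicalized so the loading of largest magnitude
#' in each component is positive.
#'
#' @param Z numeric matrix of standardized maps, one per row
#'   (`n_scans x n_pixels`). `NA` sentinels are imputed with 0 (the
#'   standardized mean).
#' @param K number of components to retain (default 10).
#' @param map_dim optional `c(rows, cols)` of the map grid, kept for
#'   rendering components as images.
#' @return An object of class `rnfl_pca`:
#' \describe{
#'   \item{mean}{pixelwise mean of the input stack (standardized units).}
#'   \item{components}{`K x n_pixels` matrix of orthonormal eigen-maps.}
#'   \item{variance_fraction}{fraction of total variance explained by each
#'     retained component (non-increasing).}
#'   \item{eigenvalues}{all `min(n-1, p)` sample covariance eigenvalues.}
#' }
#' @export
fit_rnfl_pca <- function(Z, K = 10L, map_dim = NULL) {
  stopifnot(is.matrix(Z), is.numeric(Z))
  Z <- impute_sentinel(Z)
  n <- nrow(Z); p <- ncol(Z)
  if (K < 1L || K > min(n - 1L, p))
    stop("fit_rnfl_pca: need 1 <= K <= min(n_maps - 1, n_pixels)")
  mu <- colMeans(Z)
  Xc <- sweep(Z, 2L, mu)
  G <- tcrossprod(Xc)                      # n x n Gram matrix
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  keep <- seq_len(min(n - 1L, p))
  lam <- lam[keep]
  tot <- sum(lam)
  if (tot <= 0) stop("fit_rnfl_pca: input stack has no variance")
  comps <- matrix(0, K, p)
  for (k in seq_len(K)) {
    if (lam[k] <= .Machine$double.eps * tot)
      stop("fit_rnfl_pca: requested component beyond the rank of the stack")
    v <- crossprod(Xc, eg$vectors[, k]) / sqrt(lam[k])
    imax <- which.max(abs(v))
    if (v[imax] < 0) v <- -v
    comps[k, ] <- v
  }
  structure(list(mean = mu, components = comps,
                 variance_fraction = lam[seq_len(K)] / tot,
                 eigenvalues = lam, K = K, n_fit = n,
                 map_dim = map_dim),
            class = "rnfl_pca")
}

#' @export
print.rnfl_pca <- function(x, ...) {
  cat(sprintf("RNFL PCA feature model: %d components over %d pixels (fit on %d maps)\n",
              x$K, length(x$mean), x$n_fit))
  cat(sprintf("  variance explained: %s (cumulative %.1f%%)\n",
              paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = " "),
              100 * sum(x$variance_fraction)))
  invisible(x)
}

#' Project maps onto RNFL PCA features
#'
#' Feature weights are inner products of the centered map with each
#' orthonormal component, so a map is represented as
#' `mean + sum_k w_k * component_k` plus an orthogonal residual.
#'
#' @param Z standardized map vector or matrix (maps in rows).
#' @param model an `rnfl_pca` model.
#' @return Weight matrix `n x K` (or vector for a single map).
#' @export
project_weights <- function(Z, model) {
  stopifnot(inherits(model, "rnfl_pca"))
  vec <- is.null(dim(Z))
  if (vec) Z <- matrix(Z, 1L)
  stopifnot(ncol(Z) == length(model$mean))
  Z <- impute_sentinel(Z)
  w <- sweep(Z, 2L, model$mean) %*% t(model$components)
  colnames(w) <- paste0("w", seq_len(model$K))
  if (vec) w <- drop(w)
  w
}

#' Reconstruct maps from feature weights
#'
#' @param w weight vector (length `K`) or matrix (`n x K`).
#' @param model an `rnfl_pca` model.
#' @return Reconstructed standardized map(s), rows matching `w`.
#' @export
reconstruct_map <- function(w, model) {
  stopifnot(inherits(model, "rnfl_pca"))
  vec <- is.null(dim(w))
  if (vec) w <- matrix(w, 1L)
  stopifnot(ncol(w) == model$K)
  out <- sweep(w %*% model$components, 2L, model$mean, `+`)
  if (vec) out <- drop(out)
  out
}

#' Binary change-region mask of an eigen-feature
#'
#' Thresholds the absolute loadings of component `k` at the given quantile
#' of their own distribution, yielding the mask of pixels where the
#' feature most strongly modulates RNFL thickness (the "areas of greatest
#' thinning" display for a feature).
#'
#' @param model an `rnfl_pca` model with `map_dim` set.
#' @param k component index.
#' @param quantile quantile of the absolute-loading distribution in
#'   `[0, 1)`; the mask covers roughly the top `1 - quantile` fraction of
#'   pixels.
#' @return Logical matrix of the map shape.
#' @export
feature_change_map <- function(model, k, quantile = 0.9) {
  stopifnot(inherits(model, "rnfl_pca"), k >= 1L, k <= model$K,
            quantile >= 0, quantile < 1)
  a <- abs(model$components[k, ])
  mask <- if (quantile == 0) rep(TRUE, length(a))
          else a > stats::quantile(a, quantile, names = FALSE)
  if (!is.null(model$map_dim)) matrix(mask, model$map_dim[1L], model$map_dim[2L])
  else mask
}
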