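#' Per-pixel standardization of a registered map stack
#'
#' Computes, for every pixel location, the mean and standard deviation of
#' thickness across a stack of registered maps, so that maps can be
#' transformed to zero mean and unit variance per pixel. Out-of-frame
#' sentinel pixels (`NA`) are excluded from the statistics rather than
#' zero-filled, since zero-filling would corrupt the per-pixel variance.
#' Standard deviations are floored at `eps` to guard pixels that are
#' constant across the stack.
#'
#' @param X numeric matrix, one registered map per row (`n_scans x n_pixels`);
#'   `NA` allowed.
#' @param eps variance floor (micrometers); pixels with sd below `eps` are
#'   treated as constant and standardize to 0.
#' @return An object of class `standardization_model` with fields `mu`,
#'   `sigma` (length `n_pixels`), `n_fit`, and `eps`.
#' @export
fit_standardization <- function(X, eps = 1e-6) {
  stopifnot(is.matrix(X), nrow(X) >= 2L, eps > 0)
  n_px <- colSums(!is.na(X))
  mu <- colMeans(X, na.rm = TRUE)
  dev <- sweep(X, 2L, mu)
  ss <- colSums(dev^2, na.rm = TRUE)
  v <- ifelse(n_px >= 2L, ss / pmax(n_px - 1L, 1L), 0)
  mu[n_px == 0L] <- 0
  structure(list(mu = mu, sigma = pmax(sqrt(v), eps), n_fit = nrow(X),
                 n_px = n_px, eps = eps),
            class = "standardization_model")
}

#' Apply a standardization model
#'
#' @param x numeric vector (one flattened map) or matrix (maps in rows).
#' @param model a `standardization_model` from [fit_standardization()].
#' @return Standardized values of the same shape; pixels whose training sd
#'   was at the floor return 0, `NA` sentinels are preserved.
#' @export
apply_standardization <- function(x, model) {
  stopifnot(inherits(model, "standardization_model"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1L)
  stopifnot(ncol(x) == length(model$mu))
  z <- sweep(sweep(x, 2L, model$mu), 2L, model$sigma, `/`)
  const <- model$sigma <= model$eps
  if (any(const)) z[, const] <- ifelse(is.na(z[, const]), NA_real_, 0)
  if (vec) z <- drop(z)
  z
}

# Replace out-of-frame sentinels with 0 (the standardized mean) so map
# vectors are dense for PCA.
impute_sentinel <- function(z) {
  z[is.na(z)] <- 0
  z
}
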