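#' RNFL thickness map
#'
#' A dense grid of retinal nerve fiber layer thickness (micrometers) over a
#' wide-angle OCT field, together with the two anatomical landmarks
#' (fovea and optic nerve head center) used for registration, the scan
#' laterality, and the physical pixel pitch. Coordinates are 0-based pixels
#' with `x` running along columns (temporal-nasal axis) and `y` along rows;
#' the origin is the top-left pixel.
#'
#' For a right eye (OD) in this package's convention the ONH lies to the
#' left of the fovea (smaller `x`); left-eye (OS) scans are mirror images.
#'
#' @param values numeric matrix `H x W` of thickness in micrometers. `NA`
#'   marks out-of-frame pixels (possible after resampling); finite values
#'   must be non-negative.
#' @param laterality `"OD"` or `"OS"`.
#' @param fovea,onh length-2 `(x, y)` landmark coordinates in pixels,
#'   strictly inside the grid.
#' @param mm_per_px physical pixel pitch in millimeters (isotropic).
#' @param participant_id,eye_id,visit_month optional keys tying the scan to
#'   a cohort record.
#' @param orientation `"OD"` once the map has been flipped to right-eye
#'   orientation (see [flip_to_od()]); defaults to the laterality.
#' @return An object of class `rnfl_map`.
#' @export
rnfl_map <- function(values, laterality, fovea, onh, mm_per_px,
                     participant_id = NA_character_, eye_id = NA_character_,
                     visit_month = NA_real_, orientation = laterality) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(values < 0, na.rm = TRUE)) stop("rnfl_map: negative thickness values")
  if (any(is.infinite(values))) stop("rnfl_map: non-finite thickness values")
  if (!laterality %in% c("OD", "OS")) stop("rnfl_map: laterality must be 'OD' or 'OS'")
  h <- nrow(values); w <- ncol(values)
  chk_lm <- function(p, nm) {
    if (length(p) != 2L || !all(is.finite(p)))
      stop(sprintf("rnfl_map: %s landmark must be finite (x, y)", nm))
    if (p[1L] <= 0 || p[1L] >= w - 1 || p[2L] <= 0 || p[2L] >= h - 1)
      stop(sprintf("rnfl_map: %s landmark outside the grid interior", nm))
  }
  chk_lm(fovea, "fovea"); chk_lm(onh, "onh")
  # nasal check: in OD orientation the ONH is nasal (left) of the fovea
  if (orientation == "OD" && onh[1L] >= fovea[1L])
    stop("rnfl_map: OD orientation requires ONH temporal-to-nasal ordering (onh x < fovea x)")
  if (orientation == "OS" && onh[1L] <= fovea[1L])
    stop("rnfl_map: OS orientation requires onh x > fovea x")
  stopifnot(is.numeric(mm_per_px), length(mm_per_px) == 1L, mm_per_px > 0)
  structure(list(values = values, laterality = laterality,
                 orientation = orientation,
                 fovea = as.numeric(fovea), onh = as.numeric(onh),
                 mm_per_px = mm_per_px,
                 participant_id = participant_id, eye_id = eye_id,
                 visit_month = visit_month),
            class = "rnfl_map")
}

#' @export
print.rnfl_map <- function(x, ...) {
  cat(sprintf("RNFL thickness map: %d x %d px (%.3g mm/px), %s (%s-oriented)\n",
              nrow(x$values), ncol(x$values), x$mm_per_px, x$laterality,
              x$orientation))
  cat(sprintf("  fovea (%.1f, %.1f), ONH (%.1f, %.1f); thickness %.1f-%.1f um\n",
              x$fovea[1L], x$fovea[2L], x$onh[1L], x$onh[2L],
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Bilinear sampling of a grid at fractional pixel coordinates
#'
#' @param values numeric matrix (rows = y, cols = x).
#' @param x,y numeric vectors of 0-based coordinates.
#' @return Sampled values; `NA` where the sample point falls outside the
#'   grid or touches an `NA` cell.
#' @keywords internal
bilinear_sample <- function(values, x, y) {
  h <- nrow(values); w <- ncol(values)
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x) & is.finite(y) & x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  if (!any(ok)) return(out)
  xs <- x[ok]; ys <- y[ok]
  x0 <- pmin(floor(xs), w - 2); y0 <- pmin(floor(ys), h - 2)
  fx <- xs - x0; fy <- ys - y0
  i00 <- y0 + 1 + x0 * h          # column-major linear index of (y0, x0)
  v00 <- values[i00];     v01 <- values[i00 + h]
  v10 <- values[i00 + 1]; v11 <- values[i00 + h + 1]
  out[ok] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  out
}

#' Mirror a thickness map about its vertical axis
#'
#' Pure involution: values are reversed along `x`, landmarks remapped to
#' `x' = (W - 1) - x`, and the laterality/orientation tags swapped between
#' OD and OS. Applying it twice returns the original map.
#'
#' @param map an `rnfl_map`.
#' @return The mirrored `rnfl_map`.
#' @export
mirror_map <- function(map) {
  stopifnot(inherits(map, "rnfl_map"))
  w <- ncol(map$values)
  swap <- function(l) if (l == "OD") "OS" else "OD"
  rnfl_map(values = map$values[, w:1, drop = FALSE],
           laterality = swap(map$laterality),
           fovea = c((w - 1) - map$fovea[1L], map$fovea[2L]),
           onh = c((w - 1) - map$onh[1L], map$onh[2L]),
           mm_per_px = map$mm_per_px,
           participant_id = map$participant_id, eye_id = map$eye_id,
           visit_month = map$visit_month,
           orientation = swap(map$orientation))
}

#' Flip a scan to right-eye (OD) orientation
#'
#' Left-eye scans are mirrored about the vertical axis (with landmarks
#' remapped) so that all maps share a common anatomical orientation before
#' pooling; right-eye scans pass through unchanged. The `laterality` field
#' keeps the scan's true eye, while `orientation` records that the map is
#' now OD-oriented.
#'
#' @param map an `rnfl_map`.
#' @return An OD-oriented `rnfl_map`.
#' @export
flip_to_od <- function(map) {
  stopifnot(inherits(map, "rnfl_map"))
  if (is.na(map$orientation) || !map$orientation %in% c("OD", "OS"))
    stop("flip_to_od: map orientation/laterality missing")
  if (map$orientation == "OD") return(map)
  out <- mirror_map(map)
  out$laterality <- map$laterality   # true eye is unchanged by reorientation
  out
}

#' Mean circumpapillary RNFL thickness on a circle about the ONH
#'
#' Emulates the clinically standard circle-scan summary: thickness is
#' bilinearly sampled at equally spaced angles on a circle of the given
#' radius centered on the ONH landmark and averaged.
#'
#' @param map an `rnfl_map`.
#' @param radius_mm circle radius in millimeters; the default 1.725 mm is
#'   the standard 3.45 mm-diameter scan circle.
#' @param n_angles number of equally spaced samples (>= 256).
#' @return Mean thickness on the circle, micrometers.
#' @export
extract_mean_cprnflt <- function(map, radius_mm = 1.725, n_angles = 512L) {
  stopifnot(inherits(map, "rnfl_map"), n_angles >= 256L)
  r_px <- radius_mm / map$mm_per_px
  ang <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  x <- map$onh[1L] + r_px * cos(ang)
  y <- map$onh[2L] + r_px * sin(ang)
  h <- nrow(map$values); w <- ncol(map$values)
  if (any(x < 0 | x > w - 1 | y < 0 | y > h - 1))
    stop("extract_mean_cprnflt: measurement circle exits the scan grid")
  v <- bilinear_sample(map$values, x, y)
  if (anyNA(v)) stop("extract_mean_cprnflt: circle crosses out-of-frame pixels")
  mean(v)
}

#' Resample a grid of values under a similarity transform
#'
#' @param values source matrix.
#' @param tf `similarity_transform` mapping source coordinates to output
#'   coordinates.
#' @param out_dim `c(rows, cols)` of the output grid; defaults to the
#'   source dimensions.
#' @param fill value for output pixels that map outside the source grid
#'   (default `NA`, the out-of-frame sentinel excluded from downstream
#'   statistics).
#' @return Matrix of resampled values.
#' @export
resample_values <- function(values, tf, out_dim = dim(values), fill = NA_real_) {
  stopifnot(is.matrix(values), inherits(tf, "similarity_transform"))
  h <- out_dim[1L]; w <- out_dim[2L]
  inv <- invert_transform(tf)
  xg <- rep(0:(w - 1), each = h)
  yg <- rep(0:(h - 1), times = w)
  src <- apply_transform(inv, cbind(xg, yg))
  v <- bilinear_sample(values, src[, 1L], src[, 2L])
  if (!is.na(fill)) v[is.na(v)] <- fill
  matrix(v, h, w)
}

#' Resample a thickness map into a new frame
#'
#' Applies [resample_values()] to the pixel data and transforms the
#' landmarks consistently.
#'
#' @inheritParams resample_values
#' @param map an `rnfl_map`.
#' @return The resampled `rnfl_map`.
#' @export
resample_map <- function(map, tf, out_dim = dim(map$values), fill = NA_real_) {
  stopifnot(inherits(map, "rnfl_map"))
  vals <- resample_values(map$values, tf, out_dim, fill)
  vals[!is.na(vals) & vals < 0] <- 0  # guard tiny negative interpolation overshoot
  rnfl_map(values = vals, laterality = map$laterality,
           fovea = apply_transform(tf, map$fovea),
           onh = apply_transform(tf, map$onh),
           mm_per_px = map$mm_per_px / tf$s,
           participant_id = map$participant_id, eye_id = map$eye_id,
           visit_month = map$visit_month, orientation = map$orientation)
}

#' Separable Gaussian smoothing with replicate padding
#'
#' @param values numeric matrix.
#' @param sigma kernel standard deviation in pixels.
#' @return Smoothed matrix of the same shape.
#' @keywords internal
gaussian_smooth <- function(values, sigma) {
  if (sigma <= 0) return(values)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  conv1 <- function(m) { # along rows (down columns), replicate padding
    n <- nrow(m)
    idx <- pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(values))))
}

# Variance attenuation factor of white noise under gaussian_smooth(): the
# sum of squares of the effective 2-D kernel. Used to renormalize smoothed
# noise fields back to a target marginal standard deviation.
smoothing_sd_factor <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  sum(outer(k, k)^2)^0.5
}
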