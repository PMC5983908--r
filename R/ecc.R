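#' Enhanced correlation coefficient image registration
#'
#' Aligns a moving image to a fixed image by iteratively maximizing the
#' enhanced correlation coefficient (ECC): the correlation of the zero-mean
#' image intensity vectors, which is invariant to affine photometric
#' (gain/offset) differences between scans. The motion model is Euclidean
#' (rotation + translation) by default or full similarity
#' (scale + rotation + translation); updates follow the closed-form
#' Gauss-Newton scheme for the ECC objective, run coarse-to-fine over an
#' image pyramid for robustness to larger displacements.
#'
#' Rotation and scale are parameterized about the image center. `NA`
#' pixels (out-of-frame sentinels) are replaced by the image's mean
#' intensity for the purpose of the ECC objective.
#'
#' @param moving,fixed numeric matrices of identical dimensions.
#' @param motion `"euclidean"` or `"similarity"`.
#' @param max_iters maximum iterations per pyramid level.
#' @param eps convergence threshold on the parameter update, in pixels of
#'   induced displacement at the image corner.
#' @param pyramid_levels number of pyramid levels (1 = original scale only).
#' @param init optional initial `similarity_transform` (point mapping from
#'   moving to fixed frame).
#' @return A list of class `ecc_result`:
#' \describe{
#'   \item{transform}{`similarity_transform` mapping moving-frame points to
#'     fixed-frame points, so `resample_values(moving, transform)` aligns
#'     onto `fixed`.}
#'   \item{ecc}{final enhanced correlation coefficient in `[-1, 1]`.}
#'   \item{converged}{logical; `FALSE` if the final level hit `max_iters`
#'     without the update falling below `eps`. Callers may then fall back
#'     to the initial transform or exclude the scan.}
#'   \item{iters}{iterations used at the finest level.}
#' }
#' @export
ecc_register <- function(moving, fixed, motion = c("euclidean", "similarity"),
                         max_iters = 200L, eps = 1e-4, pyramid_levels = 3L,
                         init = NULL) {
  motion <- match.arg(motion)
  stopifnot(is.matrix(moving), is.matrix(fixed),
            all(dim(moving) == dim(fixed)))
  fill_na <- function(m) {
    if (anyNA(m)) m[is.na(m)] <- mean(m, na.rm = TRUE)
    m
  }
  moving <- fill_na(moving); fixed <- fill_na(fixed)
  if (!all(is.finite(moving)) || !all(is.finite(fixed)))
    stop("ecc_register: images must be finite")

  # limit pyramid depth so the coarsest level keeps enough structure
  maxlev <- max(1L, floor(log2(min(dim(fixed)) / 24)) + 1L)
  pyramid_levels <- max(1L, min(pyramid_levels, maxlev))
  down2 <- function(m) {
    h <- floor(nrow(m) / 2) * 2L; w <- floor(ncol(m) / 2) * 2L
    m <- m[seq_len(h), seq_len(w), drop = FALSE]
    0.25 * (m[seq(1, h, 2), seq(1, w, 2)] + m[seq(2, h, 2), seq(1, w, 2)] +
            m[seq(1, h, 2), seq(2, w, 2)] + m[seq(2, h, 2), seq(2, w, 2)])
  }
  pyr_m <- list(moving); pyr_f <- list(fixed)
  if (pyramid_levels > 1L) for (l in 2:pyramid_levels) {
    pyr_m[[l]] <- down2(pyr_m[[l - 1L]])
    pyr_f[[l]] <- down2(pyr_f[[l - 1L]])
  }

  # internal warp W maps fixed coords -> moving coords, parameterized about
  # the fixed-image center; initialized from the inverse of `init`.
  p <- list(s = 1, theta = 0, tx = 0, ty = 0)
  if (!is.null(init)) {
    stopifnot(inherits(init, "similarity_transform"))
    w0 <- invert_transform(init)
    ctr0 <- c((ncol(fixed) - 1) / 2, (nrow(fixed) - 1) / 2)
    # convert origin-form to center-pivot form at full resolution
    tv <- apply_transform(w0, ctr0) - ctr0
    p <- list(s = w0$s, theta = w0$theta, tx = tv[1L], ty = tv[2L])
  }

  conv <- FALSE; iters_fin <- 0L; rho <- NA_real_
  sc0 <- 2^(pyramid_levels - 1L)
  p$tx <- p$tx / sc0; p$ty <- p$ty / sc0
  for (lev in pyramid_levels:1) {
    res <- ecc_level(pyr_m[[lev]], pyr_f[[lev]], p, motion, max_iters, eps)
    p <- res$p; rho <- res$rho
    conv <- res$converged; iters_fin <- res$iters
    if (lev > 1L) { p$tx <- p$tx * 2; p$ty <- p$ty * 2 }
  }

  ctr <- c((ncol(fixed) - 1) / 2, (nrow(fixed) - 1) / 2)
  warp <- similarity_about(s = p$s, theta = p$theta, tx = p$tx, ty = p$ty,
                           center = ctr)
  structure(list(transform = invert_transform(warp), ecc = rho,
                 converged = conv, iters = iters_fin),
            class = "ecc_result")
}

# One pyramid level of ECC Gauss-Newton iterations. `p` holds the warp
# (fixed -> moving) in center-pivot form for this level's resolution.
ecc_level <- function(moving, fixed, p, motion, max_iters, eps) {
  h <- nrow(fixed); w <- ncol(fixed)
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  # interior fixed-image sample grid (1 px margin for gradients)
  xs <- 1:(w - 2); ys <- 1:(h - 2)
  xg <- rep(xs, each = length(ys)) - ctr[1L]
  yg <- rep(ys, times = length(xs)) - ctr[2L]
  fvec <- as.vector(fixed[ys + 1L, xs + 1L])
  # moving-image gradients (central differences)
  gx_img <- matrix(0, h, w); gy_img <- matrix(0, h, w)
  gx_img[, 2:(w - 1)] <- (moving[, 3:w] - moving[, 1:(w - 2)]) / 2
  gy_img[2:(h - 1), ] <- (moving[3:h, ] - moving[1:(h - 2), ]) / 2
  diag_px <- sqrt(sum((c(w, h) - 1)^2)) / 2
  n_par <- if (motion == "similarity") 4L else 3L
  iters <- 0L; converged <- FALSE; rho <- NA_real_
  for (it in seq_len(max_iters)) {
    iters <- it
    ct <- cos(p$theta); st <- sin(p$theta)
    rx <- xg * ct - yg * st
    ry <- xg * st + yg * ct
    wx <- p$s * rx + ctr[1L] + p$tx
    wy <- p$s * ry + ctr[2L] + p$ty
    ok <- wx >= 0 & wx <= w - 1 & wy >= 0 & wy <= h - 1
    if (sum(ok) < 16L * n_par) break
    iw <- bilinear_sample(moving, wx[ok], wy[ok])
    gx <- bilinear_sample(gx_img, wx[ok], wy[ok])
    gy <- bilinear_sample(gy_img, wx[ok], wy[ok])
    # Jacobian of W wrt parameters (theta, tx, ty[, s])
    dwx_dt <- p$s * (-xg[ok] * st - yg[ok] * ct)
    dwy_dt <- p$s * ( xg[ok] * ct - yg[ok] * st)
    G <- cbind(gx * dwx_dt + gy * dwy_dt, gx, gy)
    if (motion == "similarity") G <- cbind(G, gx * rx[ok] + gy * ry[ok])
    f0 <- fvec[ok] - mean(fvec[ok])
    i0 <- iw - mean(iw)
    G0 <- sweep(G, 2L, colMeans(G))
    GtG <- crossprod(G0)
    Gty <- crossprod(G0, i0)
    Gtf <- crossprod(G0, f0)
    sol <- tryCatch(solve(GtG), error = function(e) NULL)
    if (is.null(sol)) break
    nf <- sqrt(sum(f0^2)); ni <- sqrt(sum(i0^2))
    if (nf < 1e-12 || ni < 1e-12) break
    rho <- sum(f0 * i0) / (nf * ni)
    num <- ni^2 - crossprod(Gty, sol %*% Gty)
    den <- sum(f0 * i0) - crossprod(Gtf, sol %*% Gty)
    lambda <- if (den > 1e-12) as.numeric(num / den) else ni / nf
    e <- lambda * f0 - i0
    dp <- as.vector(sol %*% crossprod(G0, e))
    p$theta <- p$theta + dp[1L]
    p$tx <- p$tx + dp[2L]; p$ty <- p$ty + dp[3L]
    if (motion == "similarity") p$s <- max(p$s + dp[4L], 1e-3)
    step_px <- abs(dp[1L]) * diag_px + sqrt(dp[2L]^2 + dp[3L]^2) +
      if (motion == "similarity") abs(dp[4L]) * diag_px else 0
    if (is.finite(step_px) && step_px < eps) { converged <- TRUE; break }
  }
  list(p = p, rho = rho, converged = converged, iters = iters)
}
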