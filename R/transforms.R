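#' Similarity transform in pixel coordinates
#'
#' A 2-D similarity transform `p' = s * R(theta) %*% p + t` acting on
#' 0-based pixel coordinates `(x = column, y = row)`. These transforms are
#' the motion model used throughout registration: landmark alignment solves
#' for one exactly, ECC refinement estimates one iteratively, and the
#' synthetic cohort generator uses them to inject known misalignments.
#'
#' @param s positive scale factor (unitless).
#' @param theta rotation angle in radians, counter-clockwise in the
#'   `(x right, y down)` pixel frame (i.e. clockwise on screen).
#' @param tx,ty translation in pixels.
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(s = 1, theta = 0, tx = 0, ty = 0) {
  stopifnot(is.numeric(s), length(s) == 1L, is.finite(s), s > 0,
            is.numeric(theta), length(theta) == 1L, is.finite(theta),
            is.numeric(tx), length(tx) == 1L, is.finite(tx),
            is.numeric(ty), length(ty) == 1L, is.finite(ty))
  structure(list(s = s, theta = theta, tx = tx, ty = ty),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity transform: s = %.6g, theta = %.6g rad (%.4g deg), t = (%.6g, %.6g) px\n",
              x$s, x$theta, x$theta * 180 / pi, x$tx, x$ty))
  invisible(x)
}

rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

#' Apply a similarity transform to points
#'
#' @param tf a `similarity_transform`.
#' @param pts an `n x 2` matrix of `(x, y)` coordinates, or a length-2 vector.
#' @return Transformed coordinates in the same shape as the input.
#' @export
apply_transform <- function(tf, pts) {
  stopifnot(inherits(tf, "similarity_transform"))
  vec <- is.null(dim(pts))
  if (vec) pts <- matrix(pts, 1L, 2L)
  stopifnot(ncol(pts) == 2L)
  out <- pts %*% t(tf$s * rotation_matrix(tf$theta))
  out[, 1L] <- out[, 1L] + tf$tx
  out[, 2L] <- out[, 2L] + tf$ty
  if (vec) out <- drop(out)
  out
}

#' Compose two similarity transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`
#' (`(a %then% b)(p) = a(b(p))`).
#'
#' @param a,b `similarity_transform` objects.
#' @return A `similarity_transform`.
#' @export
compose_transform <- function(a, b) {
  stopifnot(inherits(a, "similarity_transform"), inherits(b, "similarity_transform"))
  tv <- a$s * rotation_matrix(a$theta) %*% c(b$tx, b$ty) + c(a$tx, a$ty)
  similarity_transform(s = a$s * b$s, theta = a$theta + b$theta,
                       tx = tv[1L], ty = tv[2L])
}

#' Invert a similarity transform
#'
#' @param tf a `similarity_transform`.
#' @return The inverse `similarity_transform`.
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "similarity_transform"))
  tv <- -(1 / tf$s) * rotation_matrix(-tf$theta) %*% c(tf$tx, tf$ty)
  similarity_transform(s = 1 / tf$s, theta = -tf$theta, tx = tv[1L], ty = tv[2L])
}

#' Similarity transform about a center point
#'
#' Builds the transform `p' = s * R(theta) %*% (p - center) + center + t`,
#' i.e. rotation/scaling about `center` followed by a translation. This is
#' the natural parameterization for scan misalignment (rotation about the
#' scan center) and for ECC motion parameters.
#'
#' @param s,theta,tx,ty as in [similarity_transform()].
#' @param center length-2 `(x, y)` pivot in pixels.
#' @return A `similarity_transform` in the plain (origin-pivot) form.
#' @export
similarity_about <- function(s = 1, theta = 0, tx = 0, ty = 0, center = c(0, 0)) {
  stopifnot(length(center) == 2L, all(is.finite(center)))
  tv <- center + c(tx, ty) - s * rotation_matrix(theta) %*% center
  similarity_transform(s = s, theta = theta, tx = tv[1L], ty = tv[2L])
}

#' Exact similarity transform from two landmark pairs
#'
#' Solves for the unique similarity transform mapping the source fovea/ONH
#' pair onto the reference fovea/ONH pair. Treating points as complex
#' numbers `z' = a z + b`, the two-point system is linear and solved
#' exactly; no optimization is involved.
#'
#' @param src_fovea,src_onh source landmarks, `(x, y)` pixels.
#' @param ref_fovea,ref_onh reference landmarks, `(x, y)` pixels.
#' @return A `similarity_transform` with
#'   `apply_transform(tf, src_fovea) == ref_fovea` (and likewise for the ONH)
#'   to machine precision.
#' @export
landmark_similarity <- function(src_fovea, src_onh, ref_fovea, ref_onh) {
  as_z <- function(p) complex(real = p[1L], imaginary = p[2L])
  sf <- as_z(src_fovea); so <- as_z(src_onh)
  rf <- as_z(ref_fovea); ro <- as_z(ref_onh)
  if (Mod(sf - so) < 1e-9 || Mod(rf - ro) < 1e-9) {
    stop("landmark_similarity: fovea and ONH coincide; transform is degenerate")
  }
  a <- (rf - ro) / (sf - so)
  b <- rf - a * sf
  similarity_transform(s = Mod(a), theta = Arg(a), tx = Re(b), ty = Im(b))
}
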