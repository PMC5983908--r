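#' @keywords internal
#' Canonical landmark positions, as fractions of the grid.
#' In OD orientation the ONH sits nasally (left) of the fovea.
canonical_landmarks <- function(grid_h, grid_w) {
  list(fovea = c(0.62 * (grid_w - 1), 0.50 * (grid_h - 1)),
       onh   = c(0.30 * (grid_w - 1), 0.47 * (grid_h - 1)))
}

# Quadratic Bezier curve sampled at `n` points; control points are rows of
# a 3 x 2 matrix (mm coordinates).
bezier_points <- function(P, n = 80L) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * P[1, 1] + 2 * (1 - t) * t * P[2, 1] + t^2 * P[3, 1],
        (1 - t)^2 * P[1, 2] + 2 * (1 - t) * t * P[2, 2] + t^2 * P[3, 2])
}

# Soft ridge along a Bezier bundle trajectory: at each pixel the maximum
# over curve samples of a tapered Gaussian cross-section. `xm`/`ym` are
# matrices of mm offsets from the ONH.
bundle_field <- function(xm, ym, P, width0 = 0.45, width_grow = 0.5,
                         taper = 0.55, n = 80L) {
  B <- bezier_points(P, n)
  t <- seq(0, 1, length.out = n)
  out <- matrix(0, nrow(xm), ncol(xm))
  for (i in seq_len(n)) {
    s2 <- 2 * (width0 + width_grow * t[i])^2
    wgt <- 1 - taper * t[i]
    d2 <- (xm - B[i, 1])^2 + (ym - B[i, 2])^2
    out <- pmax(out, wgt * exp(-d2 / s2))
  }
  out
}

# Shared geometry for template and damage patterns. All distances in mm,
# y increasing downward (so superior retina has negative y offsets).
template_fields <- function(grid_h, grid_w, mm_per_px, onh_px, fovea_px,
                            arcuate_amplitude = 1) {
  x_mm <- ((0:(grid_w - 1)) - onh_px[1L]) * mm_per_px
  y_mm <- ((0:(grid_h - 1)) - onh_px[2L]) * mm_per_px
  xm <- matrix(x_mm, grid_h, grid_w, byrow = TRUE)
  ym <- matrix(y_mm, grid_h, grid_w)
  r_onh <- sqrt(xm^2 + ym^2)
  phi <- atan2(ym, xm)
  fv <- (fovea_px - onh_px) * mm_per_px
  r_fov <- sqrt((xm - fv[1L])^2 + (ym - fv[2L])^2)

  # peripapillary ring with superior/inferior double-hump modulation; the
  # modulation scales with the arcuate amplitude so amplitude 0 leaves a
  # radially symmetric annulus
  ring <- exp(-(r_onh - 1.6)^2 / (2 * 0.6^2)) *
    (1 + 0.45 * arcuate_amplitude * (-cos(2 * phi)))

  # superior and inferior arcuate bundles: arcs leaving the disc vertically
  # and sweeping temporally around the macula toward the raphe
  P_sup <- rbind(c(0.2, -1.0), c(2.2, -2.8), c(4.9, -1.0))
  P_inf <- rbind(c(0.2,  1.0), c(2.2,  2.8), c(4.9,  1.0) + c(0, 2 * fv[2L]))
  sup <- bundle_field(xm, ym, P_sup)
  inf <- bundle_field(xm, ym, P_inf)
  arc <- 0.8 * arcuate_amplitude * (sup + inf)

  dip <- 1 - 0.85 * exp(-r_fov^2 / (2 * 0.35^2))
  list(structure = ring + arc, dip = dip, sup = sup, inf = inf,
       r_onh = r_onh, r_fov = r_fov, xm = xm, ym = ym)
}

# Build the healthy OD template on an explicit grid; amplitude is solved in
# closed form so the mean thickness on the standard 3.45 mm circle hits the
# configured target.
build_template <- function(grid_h, grid_w, mm_per_px, onh_px, fovea_px,
                           target_cprnflt, background_thickness,
                           arcuate_amplitude) {
  if (grid_w < 64L || grid_h < 48L)
    stop("build_template: grid must be at least 64 x 48 px")
  fl <- template_fields(grid_h, grid_w, mm_per_px, onh_px, fovea_px,
                        arcuate_amplitude)
  circle_mean <- function(values) {
    r_px <- 1.725 / mm_per_px
    ang <- seq(0, 2 * pi, length.out = 513L)[-513L]
    mean(bilinear_sample(values, onh_px[1L] + r_px * cos(ang),
                         onh_px[2L] + r_px * sin(ang)))
  }
  c_bg <- circle_mean(background_thickness * fl$dip)
  c_s <- circle_mean(fl$structure * fl$dip)
  if (!is.finite(c_s) || c_s <= 1e-6)
    stop("build_template: measurement circle misses the ring structure")
  amp <- (target_cprnflt - c_bg) / c_s
  if (amp <= 0) stop("build_template: target cpRNFL thickness below background")
  vals <- (background_thickness + amp * fl$structure) * fl$dip
  list(values = pmax(vals, 0), fields = fl, amplitude = amp)
}

#' Healthy RNFL thickness template map
#'
#' Deterministically constructs the noise-free right-eye (OD) thickness
#' template that anchors the synthetic cohort: a peripapillary ring of
#' maximal thickness around the ONH with superior/inferior bundle
#' modulation, arcuate bundles sweeping around the macula, and a thin
#' fovea. The overall amplitude is solved so that the mean thickness on
#' the standard 3.45 mm circle equals `config$target_cprnflt`.
#'
#' @param config a [cohort_config()].
#' @return An `rnfl_map` (laterality OD) on the configured grid.
#' @export
generate_template_map <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  lm <- canonical_landmarks(config$grid_h, config$grid_w)
  tpl <- build_template(config$grid_h, config$grid_w, config$mm_per_px,
                        lm$onh, lm$fovea, config$target_cprnflt,
                        config$background_thickness, config$arcuate_amplitude)
  rnfl_map(values = tpl$values, laterality = "OD", fovea = lm$fovea,
           onh = lm$onh, mm_per_px = config$mm_per_px)
}

#' Glaucomatous damage pattern masks
#'
#' Smooth spatial masks in `[0, 1]` (peak 1) describing where each damage
#' archetype removes RNFL tissue: thinning along the inferior arcuate
#' bundle, along the superior arcuate bundle, or diffusely over the
#' macular region. An eye's thinning in the generator is
#' `severity * mask` micrometers.
#'
#' @param config a [cohort_config()].
#' @return Named list of `H x W` matrices:
#'   `inferior_arcuate`, `superior_arcuate`, `diffuse_macular`.
#' @export
damage_patterns <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  lm <- canonical_landmarks(config$grid_h, config$grid_w)
  damage_patterns_at(config$grid_h, config$grid_w, config$mm_per_px,
                     lm$onh, lm$fovea)
}

damage_patterns_at <- function(grid_h, grid_w, mm_per_px, onh_px, fovea_px) {
  fl <- template_fields(grid_h, grid_w, mm_per_px, onh_px, fovea_px)
  norm1 <- function(m) m / max(m)
  list(inferior_arcuate = norm1(fl$inf),
       superior_arcuate = norm1(fl$sup),
       diffuse_macular = norm1(exp(-fl$r_fov^2 / (2 * 2.0^2))))
}
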