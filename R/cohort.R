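#' Synthetic cohort configuration
#'
#' Parameters of the synthetic longitudinal glaucoma cohort generator. The
#' defaults reproduce the study design the analysis pipeline assumes: 93
#' glaucoma participants contributing 179 eyes and 28 healthy participants
#' contributing 56 eyes, imaged every 3 months for 2 years on a 12.0 x 9.0
#' mm wide-angle field, with an age confound between groups, spatially
#' structured glaucomatous thinning, eye-level linear progression, linked
#' visual-field scalars, and per-scan misalignment plus laterality flips.
#'
#' @param n_glaucoma_participants,n_healthy_participants participant counts.
#' @param eye_totals named vector `c(glaucoma=, healthy=)` forcing the
#'   total eye counts per group (participants are assigned one or two eyes
#'   to match), or `NULL` to sample eye counts with `p_two_eyes`.
#' @param p_two_eyes probability a participant contributes both eyes when
#'   `eye_totals` is `NULL`.
#' @param n_visits number of visits per eye (>= 1).
#' @param visit_interval_months months between visits.
#' @param grid_h,grid_w map grid size in pixels; together with `field_mm`
#'   this must give an isotropic pixel pitch.
#' @param field_mm physical scan field `c(width, height)` in mm.
#' @param age_mean,age_sd named vectors (glaucoma, healthy), years. The
#'   glaucoma group is older by default, building in the age confound.
#' @param age_range truncation range for ages, years.
#' @param target_cprnflt healthy template mean thickness on the 3.45 mm
#'   circle, micrometers.
#' @param background_thickness template background thickness, micrometers.
#' @param arcuate_amplitude relative amplitude of the arcuate-bundle and
#'   superior/inferior ring modulation (1 = default anatomy, 0 = radially
#'   symmetric ring).
#' @param severity_shape,severity_scale gamma parameters for baseline
#'   damage severity (peak micrometers of thinning) in glaucoma eyes.
#' @param pattern_weights mixture weights over the damage patterns
#'   `inferior_arcuate`, `superior_arcuate`, `diffuse_macular`.
#' @param diffuse_damage_frac fraction of each glaucoma eye's damage mask
#'   taken from a proportional (thickness-weighted) diffuse-loss mask
#'   rather than its focal pattern; glaucomatous eyes typically combine
#'   focal wedge defects with generalized loss. 0 makes damage purely
#'   focal.
#' @param progressing_fraction expected fraction of glaucoma eyes that truly
#'   progress.
#' @param progression_baseline_link log-odds of progressing per standard
#'   deviation of baseline severity (0 = progression independent of
#'   baseline damage). Positive values emulate worse-at-baseline eyes
#'   progressing more often, which is what makes progression predictable
#'   from baseline structure.
#' @param progression_slope_mean,progression_slope_sd normal parameters of
#'   the true progression slope at the pattern peak, micrometers/year
#'   (negative = thinning); draws are capped below -0.25.
#' @param healthy_slope_mean mean global aging slope, micrometers/year.
#' @param slope_sd_participant,slope_sd_eye standard deviations of the
#'   participant-level and eye-level random components of the aging
#'   slope, micrometers/year (the variance components a longitudinal
#'   mixed model should recover).
#' @param offset_sd_participant,offset_sd_eye standard deviations of the
#'   participant-level and eye-level anatomical thickness offsets,
#'   micrometers (between-individual variability in overall RNFL
#'   thickness, shared across a participant's eyes and visits).
#' @param noise_sd per-pixel measurement noise standard deviation,
#'   micrometers (after spatial smoothing renormalization).
#' @param noise_smooth_sigma Gaussian smoothing sigma (pixels) applied to
#'   the noise field to mimic spatially correlated segmentation error.
#' @param cprnflt_noise_sd per-visit measurement noise of the circle-scan
#'   mean thickness, micrometers.
#' @param cprnflt_device_offset_sd per-eye offset between the circle-scan
#'   device and the wide-angle map device, micrometers (the two
#'   instruments segment the RNFL differently, so their summaries agree
#'   only up to an eye-specific bias).
#' @param sap_md_link,fdt_md_link visual-field MD loss in dB per micrometer
#'   of map-mean RNFL deficit.
#' @param sap_psd_link,fdt_psd_link PSD increase in dB per micrometer of
#'   map-mean deficit.
#' @param functional_noise_sd,psd_noise_sd measurement noise of MD and PSD,
#'   dB.
#' @param psd_base PSD of an undamaged eye, dB.
#' @param misalign_translation_px,misalign_rotation_deg,misalign_scale
#'   half-ranges of the uniform per-scan misalignment (translation px,
#'   rotation degrees, fractional scale).
#' @param landmark_noise_px standard deviation of the simulated manual
#'   landmark-marking error, pixels.
#' @param prop_os probability that a single contributed eye is the left one.
#' @param seed mandatory integer master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_glaucoma_participants = 93L,
                          n_healthy_participants = 28L,
                          eye_totals = c(glaucoma = 179L, healthy = 56L),
                          p_two_eyes = 0.9,
                          n_visits = 9L,
                          visit_interval_months = 3,
                          grid_h = 120L, grid_w = 160L,
                          field_mm = c(12.0, 9.0),
                          age_mean = c(glaucoma = 65, healthy = 48),
                          age_sd = c(glaucoma = 10, healthy = 10),
                          age_range = c(18, 95),
                          target_cprnflt = 100,
                          background_thickness = 26,
                          arcuate_amplitude = 1,
                          severity_shape = 2, severity_scale = 20,
                          diffuse_damage_frac = 0.35,
                          pattern_weights = c(inferior_arcuate = 0.4,
                                              superior_arcuate = 0.4,
                                              diffuse_macular = 0.2),
                          progressing_fraction = 0.2,
                          progression_baseline_link = 2.5,
                          progression_slope_mean = -3.5,
                          progression_slope_sd = 1.0,
                          healthy_slope_mean = -0.4,
                          slope_sd_participant = 0.5,
                          slope_sd_eye = 0.35,
                          offset_sd_participant = 4,
                          offset_sd_eye = 3,
                          noise_sd = 2,
                          noise_smooth_sigma = 1,
                          cprnflt_noise_sd = 0.3,
                          cprnflt_device_offset_sd = 4,
                          sap_md_link = 1.0, fdt_md_link = 0.9,
                          sap_psd_link = 0.5, fdt_psd_link = 0.45,
                          functional_noise_sd = 3.0,
                          psd_noise_sd = 1.2, psd_base = 1.6,
                          misalign_translation_px = 5,
                          misalign_rotation_deg = 3,
                          misalign_scale = 0.03,
                          landmark_noise_px = 1.0,
                          prop_os = 0.5,
                          seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_glaucoma_participants >= 1, n_healthy_participants >= 1,
            n_visits >= 1, visit_interval_months > 0,
            p_two_eyes >= 0, p_two_eyes <= 1,
            prop_os >= 0, prop_os <= 1,
            progressing_fraction >= 0, progressing_fraction <= 1,
            all(field_mm > 0), grid_h >= 48L, grid_w >= 64L,
            noise_sd >= 0, target_cprnflt > background_thickness,
            misalign_translation_px >= 0, misalign_rotation_deg >= 0,
            misalign_scale >= 0, misalign_scale < 1,
            diffuse_damage_frac >= 0, diffuse_damage_frac <= 1,
            landmark_noise_px >= 0,
            abs(sum(pattern_weights) - 1) < 1e-8, all(pattern_weights >= 0))
  if (is.null(seed) || !is.finite(seed)) stop("cohort_config: seed is mandatory")
  mmx <- field_mm[1L] / grid_w
  mmy <- field_mm[2L] / grid_h
  if (abs(mmx - mmy) > 1e-9)
    stop("cohort_config: grid must give an isotropic pixel pitch ",
         "(field_mm[1]/grid_w == field_mm[2]/grid_h)")
  cfg$mm_per_px <- mmx
  if (!is.null(eye_totals)) {
    et <- eye_totals
    stopifnot(length(et) == 2L,
              et[["glaucoma"]] >= n_glaucoma_participants,
              et[["glaucoma"]] <= 2L * n_glaucoma_participants,
              et[["healthy"]] >= n_healthy_participants,
              et[["healthy"]] <= 2L * n_healthy_participants)
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("synthetic cohort config: %d glaucoma + %d healthy participants, %d visits x %g months\n",
              x$n_glaucoma_participants, x$n_healthy_participants,
              x$n_visits, x$visit_interval_months))
  cat(sprintf("  grid %d x %d px (%.3g mm/px), noise %g um, seed %s\n",
              x$grid_h, x$grid_w, x$mm_per_px, x$noise_sd,
              format(x$seed)))
  invisible(x)
}

# Intercept of the progression-probability logit so that the expected
# progressing fraction over the realized severities equals the target.
calibrate_prog_intercept <- function(z, b, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  f <- function(a) mean(stats::plogis(a + b * z)) - target
  stats::uniroot(f, c(-30, 30))$root
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a full synthetic cohort from a [cohort_config()]: per-eye damage
#' patterns, severities, and progression slopes; per-visit thickness maps
#' (template minus structured thinning plus spatially correlated noise,
#' clipped at zero); visual-field and circle-scan scalars linked linearly
#' to the integrated structural deficit; per-scan similarity misalignment
#' and laterality mirroring; and simulated manual landmark marks. The
#' result is bit-reproducible for a fixed `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A list with components
#'   \describe{
#'     \item{cohort}{class `rnfl_cohort`: `meta` (one row per scan, the
#'       clinical table), `maps` (named list of [rnfl_map()]s keyed by
#'       `scan_id`), and `config`.}
#'     \item{truth}{class `cohort_truth`: per-eye ground truth (`eyes`),
#'       per-scan applied misalignments and true landmark positions
#'       (`scans`), plus the noise-free `template` map and damage `patterns`
#'       in the canonical frame, for parameter-recovery scoring only.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  H <- config$grid_h; W <- config$grid_w
  mmpx <- config$mm_per_px
  diag_half <- sqrt(sum((c(W, H) - 1)^2)) / 2
  pad <- ceiling(config$misalign_translation_px +
                   config$misalign_rotation_deg * pi / 180 * diag_half +
                   config$misalign_scale * diag_half + 4)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  lm <- canonical_landmarks(H, W)
  onh_p <- lm$onh + pad; fov_p <- lm$fovea + pad

  tpl <- build_template(Hp, Wp, mmpx, onh_p, fov_p,
                        config$target_cprnflt, config$background_thickness,
                        config$arcuate_amplitude)
  pats_focal <- damage_patterns_at(Hp, Wp, mmpx, onh_p, fov_p)
  # effective per-eye damage mask: focal pattern blended with proportional
  # (thickness-weighted) diffuse loss
  prop_mask <- tpl$values / max(tpl$values)
  df <- config$diffuse_damage_frac
  pats <- lapply(pats_focal, function(p) (1 - df) * p + df * prop_mask)
  crop_r <- pad + seq_len(H); crop_c <- pad + seq_len(W)

  r_px <- 1.725 / mmpx
  ang <- seq(0, 2 * pi, length.out = 513L)[-513L]
  cx <- onh_p[1L] + r_px * cos(ang); cy <- onh_p[2L] + r_px * sin(ang)
  circle_mean <- function(vals) mean(bilinear_sample(vals, cx, cy))
  pat_circle <- vapply(pats, circle_mean, numeric(1))
  pat_mapmean <- vapply(pats, function(p) mean(p[crop_r, crop_c]), numeric(1))

  ## participants -------------------------------------------------------
  n_g <- config$n_glaucoma_participants
  n_h <- config$n_healthy_participants
  part <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n_g + n_h)),
    group = rep(c("glaucoma", "healthy"), c(n_g, n_h)),
    stringsAsFactors = FALSE)
  part$age <- c(rnorm_trunc(n_g, config$age_mean[["glaucoma"]],
                            config$age_sd[["glaucoma"]],
                            config$age_range[1L], config$age_range[2L]),
                rnorm_trunc(n_h, config$age_mean[["healthy"]],
                            config$age_sd[["healthy"]],
                            config$age_range[1L], config$age_range[2L]))
  part$sex <- sample(c("F", "M"), n_g + n_h, replace = TRUE)

  n_eyes_for <- function(n_p, total) {
    two <- rep(1L, n_p)
    two[sample.int(n_p, total - n_p)] <- 2L
    two
  }
  if (!is.null(config$eye_totals)) {
    part$n_eyes <- 0L
    part$n_eyes[part$group == "glaucoma"] <-
      n_eyes_for(n_g, config$eye_totals[["glaucoma"]])
    part$n_eyes[part$group == "healthy"] <-
      n_eyes_for(n_h, config$eye_totals[["healthy"]])
  } else {
    part$n_eyes <- 1L + stats::rbinom(n_g + n_h, 1L, config$p_two_eyes)
  }

  ## eyes ---------------------------------------------------------------
  lat_list <- lapply(seq_len(nrow(part)), function(i) {
    if (part$n_eyes[i] == 2L) c("OD", "OS")
    else if (stats::runif(1) < config$prop_os) "OS" else "OD"
  })
  eyes <- data.frame(
    participant_id = rep(part$participant_id, lengths(lat_list)),
    laterality = unlist(lat_list), stringsAsFactors = FALSE)
  eyes <- merge(eyes, part[c("participant_id", "group", "age", "sex")],
                by = "participant_id", sort = FALSE)
  eyes$eye_id <- paste0(eyes$participant_id, "_", eyes$laterality)
  n_eye <- nrow(eyes)

  # anatomical thickness offsets and aging-slope variance components,
  # decomposed into participant-shared and eye-specific parts
  part$slope_p <- stats::rnorm(nrow(part), 0, config$slope_sd_participant)
  part$offset_p <- stats::rnorm(nrow(part), 0, config$offset_sd_participant)
  pi_of_eye <- match(eyes$participant_id, part$participant_id)
  eyes$aging_slope <- config$healthy_slope_mean + part$slope_p[pi_of_eye] +
    stats::rnorm(n_eye, 0, config$slope_sd_eye)
  eyes$anat_offset <- part$offset_p[pi_of_eye] +
    stats::rnorm(n_eye, 0, config$offset_sd_eye)
  eyes$device_offset <- stats::rnorm(n_eye, 0, config$cprnflt_device_offset_sd)
  eyes$pattern <- NA_character_
  eyes$severity <- 0
  eyes$progressing <- FALSE
  eyes$prog_slope <- 0
  ig <- which(eyes$group == "glaucoma")
  if (length(ig) > 0L) {
    eyes$pattern[ig] <- sample(names(config$pattern_weights), length(ig),
                               replace = TRUE, prob = config$pattern_weights)
    eyes$severity[ig] <- stats::rgamma(length(ig), shape = config$severity_shape,
                                       scale = config$severity_scale)
    sev <- eyes$severity[ig]
    z <- if (stats::sd(sev) > 0) (sev - mean(sev)) / stats::sd(sev) else rep(0, length(sev))
    a <- calibrate_prog_intercept(z, config$progression_baseline_link,
                                  config$progressing_fraction)
    p_prog <- stats::plogis(a + config$progression_baseline_link * z)
    eyes$progressing[ig] <- stats::runif(length(ig)) < p_prog
    ipr <- ig[eyes$progressing[ig]]
    eyes$prog_slope[ipr] <- pmin(stats::rnorm(length(ipr),
                                              config$progression_slope_mean,
                                              config$progression_slope_sd),
                                 -0.25)
  }
  eyes$pat_circle <- ifelse(is.na(eyes$pattern), 0, pat_circle[eyes$pattern])
  eyes$pat_mapmean <- ifelse(is.na(eyes$pattern), 0, pat_mapmean[eyes$pattern])
  eyes$cprnflt_slope_true <- eyes$aging_slope + eyes$prog_slope * eyes$pat_circle
  eyes$baseline_deficit <- eyes$severity * eyes$pat_mapmean

  ## scans --------------------------------------------------------------
  months <- seq(0, by = config$visit_interval_months,
                length.out = config$n_visits)
  noise_norm <- smoothing_sd_factor(config$noise_smooth_sigma)
  ctr_p <- c((Wp - 1) / 2, (Hp - 1) / 2)
  crop_tf <- similarity_transform(1, 0, -pad, -pad)

  meta <- vector("list", n_eye * config$n_visits)
  scans_gt <- vector("list", n_eye * config$n_visits)
  maps <- vector("list", n_eye * config$n_visits)
  k <- 0L
  for (e in seq_len(n_eye)) {
    pat_pad <- if (is.na(eyes$pattern[e])) NULL else pats[[eyes$pattern[e]]]
    for (vi in seq_along(months)) {
      k <- k + 1L
      t_yr <- months[vi] / 12
      clean <- tpl$values + eyes$anat_offset[e] + eyes$aging_slope[e] * t_yr
      if (!is.null(pat_pad)) {
        clean <- clean + (eyes$prog_slope[e] * t_yr - eyes$severity[e]) * pat_pad
      }
      clean <- pmax(clean, 0)
      if (config$noise_sd > 0) {
        eps <- gaussian_smooth(matrix(stats::rnorm(Hp * Wp), Hp, Wp),
                               config$noise_smooth_sigma)
        noisy <- pmax(clean + eps * (config$noise_sd / noise_norm), 0)
      } else noisy <- clean

      cprnflt <- circle_mean(noisy) + eyes$device_offset[e] +
        stats::rnorm(1, 0, config$cprnflt_noise_sd)
      d <- (eyes$severity[e] - eyes$prog_slope[e] * t_yr) * eyes$pat_mapmean[e] -
        eyes$aging_slope[e] * t_yr
      sap_md <- -config$sap_md_link * d + stats::rnorm(1, 0, config$functional_noise_sd)
      fdt_md <- -config$fdt_md_link * d + stats::rnorm(1, 0, config$functional_noise_sd)
      sap_psd <- max(config$psd_base + config$sap_psd_link * d +
                       stats::rnorm(1, 0, config$psd_noise_sd), 0.2)
      fdt_psd <- max(config$psd_base + config$fdt_psd_link * d +
                       stats::rnorm(1, 0, config$psd_noise_sd), 0.2)

      vals_p <- noisy; fov_s <- fov_p; onh_s <- onh_p
      if (eyes$laterality[e] == "OS") {
        vals_p <- vals_p[, Wp:1, drop = FALSE]
        fov_s <- c((Wp - 1) - fov_p[1L], fov_p[2L])
        onh_s <- c((Wp - 1) - onh_p[1L], onh_p[2L])
      }
      mis_s <- stats::runif(1, 1 - config$misalign_scale, 1 + config$misalign_scale)
      mis_th <- stats::runif(1, -1, 1) * config$misalign_rotation_deg * pi / 180
      mis_t <- stats::runif(2, -1, 1) * config$misalign_translation_px
      mis <- similarity_about(s = mis_s, theta = mis_th,
                              tx = mis_t[1L], ty = mis_t[2L], center = ctr_p)
      total <- compose_transform(crop_tf, mis)
      scan_vals <- resample_values(vals_p, total, out_dim = c(H, W), fill = 0)
      fov_true <- apply_transform(total, fov_s)
      onh_true <- apply_transform(total, onh_s)
      clamp <- function(p) c(min(max(p[1L], 1.5), W - 2.5),
                             min(max(p[2L], 1.5), H - 2.5))
      fov_mark <- clamp(fov_true + stats::rnorm(2, 0, config$landmark_noise_px))
      onh_mark <- clamp(onh_true + stats::rnorm(2, 0, config$landmark_noise_px))

      scan_id <- sprintf("%s_V%02d", eyes$eye_id[e], months[vi])
      maps[[k]] <- rnfl_map(values = pmax(scan_vals, 0),
                            laterality = eyes$laterality[e],
                            fovea = fov_mark, onh = onh_mark,
                            mm_per_px = mmpx,
                            participant_id = eyes$participant_id[e],
                            eye_id = eyes$eye_id[e],
                            visit_month = months[vi])
      names(maps)[k] <- scan_id
      meta[[k]] <- data.frame(
        scan_id = scan_id, participant_id = eyes$participant_id[e],
        eye_id = eyes$eye_id[e], laterality = eyes$laterality[e],
        group = eyes$group[e], age = eyes$age[e], sex = eyes$sex[e],
        visit_month = months[vi], sap_md = sap_md, sap_psd = sap_psd,
        fdt_md = fdt_md, fdt_psd = fdt_psd, mean_cprnflt = cprnflt,
        stringsAsFactors = FALSE)
      scans_gt[[k]] <- data.frame(
        scan_id = scan_id, eye_id = eyes$eye_id[e], visit_month = months[vi],
        mis_s = mis_s, mis_theta = mis_th, mis_tx = mis_t[1L], mis_ty = mis_t[2L],
        fovea_true_x = fov_true[1L], fovea_true_y = fov_true[2L],
        onh_true_x = onh_true[1L], onh_true_y = onh_true[2L],
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  scans_gt <- do.call(rbind, scans_gt)

  template_map <- rnfl_map(values = tpl$values[crop_r, crop_c],
                           laterality = "OD", fovea = lm$fovea, onh = lm$onh,
                           mm_per_px = mmpx)
  cohort <- structure(list(meta = meta, maps = maps, config = config),
                      class = "rnfl_cohort")
  truth <- structure(list(
    eyes = eyes, scans = scans_gt, template = template_map,
    patterns = lapply(pats_focal, function(p) p[crop_r, crop_c]),
    patterns_effective = lapply(pats, function(p) p[crop_r, crop_c])),
    class = "cohort_truth")
  list(cohort = cohort, truth = truth)
}

#' @export
print.rnfl_cohort <- function(x, ...) {
  m <- x$meta
  cat(sprintf("RNFL cohort: %d scans, %d eyes, %d participants (%d glaucoma / %d healthy eyes)\n",
              nrow(m), length(unique(m$eye_id)),
              length(unique(m$participant_id)),
              length(unique(m$eye_id[m$group == "glaucoma"])),
              length(unique(m$eye_id[m$group == "healthy"]))))
  invisible(x)
}
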