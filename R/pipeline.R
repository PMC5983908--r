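#' Run the full RNFL feature-analysis pipeline
#'
#' Orchestrates the complete analysis on a synthetic cohort (or one read
#' from disk): generation, spatial normalization (flip, landmark
#' alignment, ECC refinement), per-pixel standardization, PCA feature
#' extraction, age-adjusted association testing, participant-based
#' leave-one-out glaucoma detection with age-controlled bootstrap AUC
#' comparisons, and mixed-effects progression labeling plus
#' baseline-only progression prediction. All randomness derives from
#' `config$seed` (cohort) and `seed + 1, + 2, ...` (bootstrap stages), so
#' a rerun with the same configuration reproduces the report exactly.
#'
#' @param config a [cohort_config()], or the path to a YAML file of one,
#'   or an `rnfl_cohort` already generated/loaded.
#' @param K number of PCA features retained (default 10).
#' @param n_boot bootstrap replicates for AUC estimation.
#' @param ecc_refine run the ECC refinement registration stage.
#' @param detection_models comparator models for glaucoma detection.
#' @param progression_measures measurements used to define progression
#'   ground truth.
#' @param out_dir optional directory; when given, the report is written
#'   as JSON, tables as CSV, and component/change-map images as PNG.
#' @return A list of class `run_report` with elements `config`, `counts`,
#'   `registration`, `variance_explained`, `associations`, `detection`,
#'   `progression`, and `exclusions`.
#' @export
run_pipeline <- function(config = cohort_config(), K = 10L, n_boot = 1000L,
                         ecc_refine = TRUE,
                         detection_models = c("pca", "cprnflt", "sap_md",
                                              "fdt_md"),
                         progression_measures = c("mean_cprnflt", "sap_md",
                                                  "fdt_md"),
                         out_dir = NULL) {
  if (is.character(config)) config <- read_config_yaml(config)
  if (inherits(config, "cohort_config")) {
    gen <- generate_cohort(config)
    cohort <- gen$cohort
  } else if (inherits(config, "rnfl_cohort")) {
    cohort <- config
    config <- cohort$config
    if (is.null(config)) stop("run_pipeline: cohort carries no config/seed")
  } else stop("run_pipeline: config must be a cohort_config, YAML path, or rnfl_cohort")
  seed <- config$seed

  ## registration -------------------------------------------------------
  reg <- register_cohort(cohort, ecc_refine = ecc_refine)
  excl <- reg$meta$scan_id[!is.na(reg$meta$ecc_converged) &
                             !reg$meta$ecc_converged]
  exclusions <- if (length(excl) > 0L)
    data.frame(scan_id = excl, reason = "ECC refinement did not converge; landmark-only alignment kept",
               stringsAsFactors = FALSE)
  else data.frame(scan_id = character(), reason = character())

  ## features (full-cohort model, for reporting) ------------------------
  std <- fit_standardization(reg$X)
  Z <- apply_standardization(reg$X, std)
  pca <- fit_rnfl_pca(Z, K = K, map_dim = reg$map_dim)
  W_all <- project_weights(Z, pca)

  ## associations on baseline visits ------------------------------------
  base <- reg$meta$visit_month == min(reg$meta$visit_month)
  W_base <- W_all[base, , drop = FALSE]
  meta_base <- reg$meta[base, ]
  assoc <- association_table(W_base, meta_base)
  mv <- lapply(c(mean_cprnflt = "mean_cprnflt", sap_md = "sap_md",
                 fdt_md = "fdt_md"),
               function(msr) multivariate_r2(W_base, meta_base[[msr]],
                                             meta_base$age))

  ## glaucoma detection --------------------------------------------------
  scores <- loo_scores(reg, K = K, models = detection_models)
  det_auc <- list(); det_cmp <- list()
  for (mod in detection_models) {
    s <- scores[scores$model == mod, ]
    det_auc[[mod]] <- age_controlled_bootstrap_auc(
      s$prob, s$label, s$age, s$participant_id,
      n_boot = n_boot, seed = seed + 1L)
  }
  s_pca <- scores[scores$model == "pca", ]
  for (mod in setdiff(detection_models, "pca")) {
    s <- scores[scores$model == mod, ]
    stopifnot(identical(s$scan_id, s_pca$scan_id))
    det_cmp[[mod]] <- compare_auc(s_pca$prob, s$prob, s$label, s$age,
                                  s$participant_id, n_boot = n_boot,
                                  seed = seed + 2L)
  }

  ## progression ----------------------------------------------------------
  progression <- NULL
  if (config$n_visits >= 3L) {
    progression <- list()
    scalar_of <- c(mean_cprnflt = "cprnflt", sap_md = "sap_md",
                   fdt_md = "fdt_md")
    for (msr in progression_measures) {
      pl <- tryCatch(progression_labels(reg$meta, msr),
                     error = function(e) e)
      if (inherits(pl, "error")) {
        progression[[msr]] <- list(error = conditionMessage(pl))
        next
      }
      pred_pca <- tryCatch(
        predict_progression_from_baseline(reg, pl, model = "pca", K = K,
                                          n_boot = n_boot, seed = seed + 3L),
        error = function(e) e)
      pred_scalar <- tryCatch(
        predict_progression_from_baseline(reg, pl, model = scalar_of[[msr]],
                                          n_boot = n_boot, seed = seed + 3L),
        error = function(e) e)
      cmp <- NULL
      if (!inherits(pred_pca, "error") && !inherits(pred_scalar, "error")) {
        unit <- paste(pred_pca$scores$participant_id,
                      pred_pca$scores$progressing)
        cmp <- compare_auc(pred_pca$scores$prob, pred_scalar$scores$prob,
                           pred_pca$scores$progressing, pred_pca$scores$age,
                           unit, n_boot = n_boot, seed = seed + 4L)
      }
      progression[[msr]] <- list(
        labels = pl,
        pca = if (inherits(pred_pca, "error")) list(error = conditionMessage(pred_pca)) else pred_pca,
        scalar = if (inherits(pred_scalar, "error")) list(error = conditionMessage(pred_scalar)) else pred_scalar,
        comparison = cmp)
    }
  } else {
    progression <- list(skipped = sprintf(
      "insufficient visits for progression analysis (%d < 3)", config$n_visits))
  }

  report <- structure(list(
    config = config,
    counts = list(
      n_scans = nrow(reg$meta),
      n_eyes = length(unique(reg$meta$eye_id)),
      n_participants = length(unique(reg$meta$participant_id)),
      n_glaucoma_eyes = length(unique(reg$meta$eye_id[reg$meta$group == "glaucoma"])),
      n_healthy_eyes = length(unique(reg$meta$eye_id[reg$meta$group == "healthy"]))),
    registration = list(
      n_flipped = sum(reg$flipped),
      n_ecc_nonconverged = length(excl)),
    variance_explained = data.frame(component = seq_len(K),
                                    variance_fraction = pca$variance_fraction),
    associations = assoc,
    multivariate = mv,
    detection = list(scores = scores, auc = det_auc, comparisons = det_cmp),
    progression = progression,
    exclusions = exclusions,
    models = list(standardization = std, pca = pca),
    registered = reg),
    class = "run_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("RNFL PCA pipeline report\n")
  cat(sprintf("  cohort: %d scans / %d eyes / %d participants\n",
              x$counts$n_scans, x$counts$n_eyes, x$counts$n_participants))
  cat(sprintf("  variance explained by %d features: %.1f%%\n",
              nrow(x$variance_explained),
              100 * sum(x$variance_explained$variance_fraction)))
  for (mod in names(x$detection$auc))
    cat(sprintf("  detection AUC (%s): %.3f\n", mod, x$detection$auc[[mod]]$auc))
  if (!is.null(x$progression$skipped)) {
    cat("  progression:", x$progression$skipped, "\n")
  } else {
    for (msr in names(x$progression)) {
      p <- x$progression[[msr]]
      if (!is.null(p$error)) { cat(sprintf("  progression (%s): %s\n", msr, p$error)); next }
      cat(sprintf("  progression (%s): %d/%d progressing; baseline PCA AUC %.3f\n",
                  msr, p$labels$counts[["progressing"]],
                  nrow(p$labels$labels),
                  if (!is.null(p$pca$auc)) p$pca$auc$auc else NA))
    }
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (summary numbers), CSV tables (variance explained,
#' associations, detection scores, ROC coordinates, progression labels),
#' and PNG images of the eigen-features and their change-region masks.
#' Every figure is a rendering of a table that is also written.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  wcsv(report$variance_explained, "variance_explained.csv")
  wcsv(report$associations, "associations.csv")
  wcsv(report$detection$scores, "detection_scores.csv")
  wcsv(report$exclusions, "exclusions.csv")
  roc_all <- do.call(rbind, lapply(names(report$detection$auc), function(mod) {
    s <- report$detection$scores[report$detection$scores$model == mod, ]
    cbind(model = mod, roc_points(s$prob, s$label))
  }))
  wcsv(roc_all, "detection_roc.csv")
  if (is.null(report$progression$skipped)) {
    labs <- do.call(rbind, lapply(report$progression, function(p)
      if (!is.null(p$labels)) p$labels$labels else NULL))
    if (!is.null(labs)) wcsv(labs, "progression_labels.csv")
  }

  pca <- report$models$pca
  if (!is.null(pca$map_dim)) {
    for (k in seq_len(pca$K)) {
      comp <- matrix(pca$components[k, ], pca$map_dim[1L], pca$map_dim[2L])
      png_path <- file.path(dir, sprintf("feature_%02d.png", k))
      rng <- max(abs(comp))
      png::writePNG((comp + rng) / (2 * rng), target = png_path)
      mask <- feature_change_map(pca, k, 0.9)
      png::writePNG(mask * 1, target = file.path(dir, sprintf("feature_%02d_mask.png", k)))
    }
  }

  js <- list(
    seed = report$config$seed,
    counts = report$counts,
    registration = report$registration,
    variance_fraction = report$variance_explained$variance_fraction,
    variance_explained_total = sum(report$variance_explained$variance_fraction),
    multivariate_r2 = lapply(report$multivariate, function(m) m$r2),
    detection_auc = lapply(report$detection$auc, function(a)
      list(auc = a$auc, ci = a$ci, naive = a$naive_auc)),
    detection_comparisons = lapply(report$detection$comparisons, function(cmp)
      list(delta = cmp$delta, p = cmp$p)),
    progression = if (!is.null(report$progression$skipped))
      report$progression$skipped
    else lapply(report$progression, function(p) {
      if (!is.null(p$error)) return(list(error = p$error))
      list(n_progressing = unname(p$labels$counts[["progressing"]]),
           n_labeled = nrow(p$labels$labels),
           n_excluded = p$labels$n_excluded,
           threshold = p$labels$dist$threshold,
           method = p$labels$dist$method,
           auc_pca = if (!is.null(p$pca$auc)) list(auc = p$pca$auc$auc, ci = p$pca$auc$ci) else NULL,
           auc_scalar = if (!is.null(p$scalar$auc)) list(auc = p$scalar$auc$auc, ci = p$scalar$auc$ci) else NULL,
           comparison_p = if (!is.null(p$comparison)) p$comparison$p else NULL)
    }),
    exclusions = report$exclusions)
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
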