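#' Normative rate-of-change distribution from healthy eyes
#'
#' Fits a linear mixed-effects model to the healthy eyes' longitudinal
#' measurements — fixed intercept and time slope, with random intercepts
#' and slopes per participant and per eye nested in participant (REML) —
#' and derives each healthy eye's rate of change as the fixed slope plus
#' its participant- and eye-level random slopes. The normative limit of
#' "fast" change is the 95th percentile of the \emph{estimated population
#' distribution} of rates — fixed slope plus the normal quantile times
#' the square root of the summed slope variance components — in the
#' worsening direction (for thickness and MD, worsening is more negative,
#' so the limit is the 5th-percentile quantile). Taking an empirical
#' quantile of the per-eye predicted rates instead would be
#' anti-conservative: best linear unbiased predictions are shrunken
#' toward the fixed slope, pulling the limit inward. A singular
#' mixed-model fit falls back to per-eye OLS slopes with an empirical
#' quantile threshold, flagged in the result.
#'
#' @param visits data frame with columns `participant_id`, `eye_id`,
#'   `visit_month`, and the measurement column.
#' @param measurement name of the measurement column (e.g.
#'   `"mean_cprnflt"`, `"sap_md"`, `"fdt_md"`).
#' @param min_eyes,min_visits minimum data requirements.
#' @param worse_direction `-1` if worsening means a more negative slope
#'   (the case for thickness and MD measures), `+1` otherwise.
#' @param percentile normative percentile in the worsening direction
#'   (default 0.95).
#' @return An object of class `healthy_rate_dist`: per-eye `slopes`
#'   (units/year), `threshold`, `worse_direction`, `fixed_slope`,
#'   `method` (`"lmm"` or `"ols"`), `singular` flag.
#' @export
fit_healthy_rate_distribution <- function(visits, measurement,
                                          min_eyes = 10L, min_visits = 3L,
                                          worse_direction = -1,
                                          percentile = 0.95) {
  stopifnot(measurement %in% names(visits),
            worse_direction %in% c(-1, 1))
  d <- data.frame(pid = visits$participant_id, eid = visits$eye_id,
                  years = visits$visit_month / 12,
                  y = visits[[measurement]])
  d <- d[stats::complete.cases(d), ]
  nv <- table(d$eid)
  keep <- names(nv)[nv >= min_visits]
  d <- d[d$eid %in% keep, ]
  if (length(unique(d$eid)) < min_eyes)
    stop(sprintf("fit_healthy_rate_distribution: need >= %d eyes with >= %d visits",
                 min_eyes, min_visits))
  singular <- FALSE
  slopes <- NULL
  method <- "lmm"
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ years + (years | pid) + (years | eid), data = d,
                 REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)))),
    error = function(e) NULL)
  rate_sd <- NA_real_
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
    fx <- lme4::fixef(fit)[["years"]]
    re <- lme4::ranef(fit)
    eids <- unique(d$eid)
    pid_of <- d$pid[match(eids, d$eid)]
    sl_p <- re$pid[match(pid_of, rownames(re$pid)), "years"]
    sl_e <- re$eid[match(eids, rownames(re$eid)), "years"]
    sl_p[is.na(sl_p)] <- 0; sl_e[is.na(sl_e)] <- 0
    slopes <- fx + sl_p + sl_e
    names(slopes) <- eids
    fixed_slope <- fx
    fixed_slope_se <- sqrt(as.matrix(stats::vcov(fit))["years", "years"])
    vc <- as.data.frame(lme4::VarCorr(fit))
    slope_vars <- vc$vcov[!is.na(vc$var1) & vc$var1 == "years" &
                            is.na(vc$var2) & vc$grp %in% c("pid", "eid")]
    rate_sd <- sqrt(sum(slope_vars))
  } else {
    singular <- TRUE
    method <- "ols"
    eids <- unique(d$eid)
    slopes <- vapply(eids, function(e) {
      dd <- d[d$eid == e, ]
      unname(stats::coef(stats::lm(y ~ years, data = dd))[2L])
    }, numeric(1))
    names(slopes) <- eids
    fixed_slope <- mean(slopes)
    fixed_slope_se <- stats::sd(slopes) / sqrt(length(slopes))
  }
  q <- if (worse_direction < 0) 1 - percentile else percentile
  threshold <- if (method == "lmm" && is.finite(rate_sd)) {
    fixed_slope + stats::qnorm(q) * rate_sd
  } else {
    unname(stats::quantile(slopes, q, names = FALSE))
  }
  structure(list(measurement = measurement, slopes = slopes,
                 threshold = threshold, rate_sd = rate_sd,
                 worse_direction = worse_direction, percentile = percentile,
                 fixed_slope = fixed_slope, fixed_slope_se = fixed_slope_se,
                 method = method,
                 singular = singular, n_eyes = length(slopes)),
            class = "healthy_rate_dist")
}

#' @export
print.healthy_rate_dist <- function(x, ...) {
  cat(sprintf("healthy rate distribution for %s: %d eyes, fixed slope %.3f/yr, %s%% limit %.3f/yr (%s fit)\n",
              x$measurement, x$n_eyes, x$fixed_slope,
              format(100 * x$percentile), x$threshold, x$method))
  invisible(x)
}

#' Per-eye OLS rate of change
#'
#' Ordinary least-squares slope of a measurement against time in years,
#' with a two-sided t-test of the slope against zero. A series with zero
#' residual variance returns `p = 0` for a nonzero slope and `p = 1` for
#' a flat series.
#'
#' @param visit_month visit times in months.
#' @param values measurement values.
#' @return One-row data frame of class `rate_estimate`: `slope`
#'   (units/year), `se`, `p`, `n_visits`.
#' @export
eye_rate_ols <- function(visit_month, values) {
  cc <- stats::complete.cases(visit_month, values)
  tm <- visit_month[cc] / 12; y <- values[cc]
  n <- length(y)
  if (n < 3L) stop("eye_rate_ols: need at least 3 visits")
  fit <- stats::lm(y ~ tm)
  slope <- unname(stats::coef(fit)[2L])
  rss <- sum(stats::residuals(fit)^2)
  sxx <- sum((tm - mean(tm))^2)
  if (rss < 1e-20) {
    se <- 0
    p <- if (abs(slope) < 1e-12) 1 else 0
  } else {
    se <- sqrt(rss / (n - 2L) / sxx)
    p <- 2 * stats::pt(abs(slope / se), df = n - 2L, lower.tail = FALSE)
  }
  out <- data.frame(slope = slope, se = se, p = p, n_visits = n)
  class(out) <- c("rate_estimate", class(out))
  out
}

#' Classify glaucoma eyes as progressing or stable
#'
#' An eye is labeled progressing when its OLS rate of change is strictly
#' worse than the healthy normative limit (in the worsening direction)
#' \emph{and} significantly different from zero (`p < 0.05`); otherwise
#' stable.
#'
#' @param rates data frame with columns `eye_id`, `slope`, `p` (one row
#'   per glaucoma eye), e.g. built from [eye_rate_ols()].
#' @param dist a `healthy_rate_dist` for the same measurement.
#' @param alpha significance level of the nonzero-slope arm.
#' @return Data frame: `eye_id`, `slope`, `p`, `progressing` (logical),
#'   `label` (`"progressing"`/`"stable"`).
#' @export
classify_progression <- function(rates, dist, alpha = 0.05) {
  stopifnot(inherits(dist, "healthy_rate_dist"),
            all(c("eye_id", "slope", "p") %in% names(rates)))
  worse <- if (dist$worse_direction < 0) rates$slope < dist$threshold
           else rates$slope > dist$threshold
  prog <- worse & rates$p < alpha
  data.frame(eye_id = rates$eye_id, measurement = dist$measurement,
             slope = rates$slope, p = rates$p, progressing = prog,
             label = ifelse(prog, "progressing", "stable"),
             stringsAsFactors = FALSE)
}

#' Progression ground-truth labels for one measurement
#'
#' Convenience wrapper: fits the healthy normative rate distribution,
#' estimates per-eye OLS rates for glaucoma eyes with enough visits, and
#' applies the progressing/stable criterion. Eyes with fewer than
#' `min_visits` visits are excluded and counted.
#'
#' @param meta cohort clinical table (one row per scan) with `group`,
#'   `participant_id`, `eye_id`, `visit_month`, and the measurement.
#' @param measurement measurement column name.
#' @inheritParams fit_healthy_rate_distribution
#' @return List of class `progression_labels`: `labels` (data frame),
#'   `dist`, `n_excluded`, `counts` (progressing / stable).
#' @export
progression_labels <- function(meta, measurement, min_visits = 3L,
                               worse_direction = -1, percentile = 0.95) {
  healthy <- meta[meta$group == "healthy", ]
  dist <- fit_healthy_rate_distribution(healthy, measurement,
                                        min_visits = min_visits,
                                        worse_direction = worse_direction,
                                        percentile = percentile)
  glaucoma <- meta[meta$group == "glaucoma", ]
  eids <- unique(glaucoma$eye_id)
  rates <- list(); excluded <- character()
  for (e in eids) {
    d <- glaucoma[glaucoma$eye_id == e, ]
    cc <- sum(stats::complete.cases(d$visit_month, d[[measurement]]))
    if (cc < min_visits) { excluded <- c(excluded, e); next }
    r <- eye_rate_ols(d$visit_month, d[[measurement]])
    rates[[length(rates) + 1L]] <- data.frame(eye_id = e, slope = r$slope,
                                              p = r$p, stringsAsFactors = FALSE)
  }
  rates <- do.call(rbind, rates)
  labels <- classify_progression(rates, dist)
  structure(list(labels = labels, dist = dist,
                 n_excluded = length(excluded), excluded = excluded,
                 counts = c(progressing = sum(labels$progressing),
                            stable = sum(!labels$progressing))),
            class = "progression_labels")
}

#' @export
print.progression_labels <- function(x, ...) {
  n <- nrow(x$labels)
  cat(sprintf("progression labels (%s): %d/%d glaucoma eyes progressing (%.1f%%), %d excluded\n",
              x$dist$measurement, x$counts[["progressing"]], n,
              100 * x$counts[["progressing"]] / n, x$n_excluded))
  invisible(x)
}

#' Predict progression from baseline data alone
#'
#' Among glaucoma eyes with progression labels, evaluates how well
#' baseline data predicts the progressing/stable label: a
#' participant-based leave-one-out logistic model on either the first
#' `K` baseline PCA feature weights (standardization and PCA refit
#' within each training fold on all training scans) or a baseline
#' clinical scalar, scored by age-controlled bootstrap AUC.
#'
#' @param registered a `registered_cohort`.
#' @param labels a `progression_labels` object (or its `labels` data
#'   frame).
#' @param model `"pca"`, `"cprnflt"`, `"sap_md"`, or `"fdt_md"`.
#' @param K number of PCA features.
#' @param n_boot,seed,bin_width passed to
#'   [age_controlled_bootstrap_auc()].
#' @return List of class `progression_prediction`: per-eye baseline
#'   `scores` data frame and the `boot_auc` evaluation.
#' @export
predict_progression_from_baseline <- function(registered, labels,
                                              model = c("pca", "cprnflt",
                                                        "sap_md", "fdt_md"),
                                              K = 10L, n_boot = 2000L,
                                              seed = 1L, bin_width = 5) {
  stopifnot(inherits(registered, "registered_cohort"))
  model <- match.arg(model)
  lab <- if (inherits(labels, "progression_labels")) labels$labels else labels
  meta <- registered$meta
  base_idx <- which(meta$visit_month == min(meta$visit_month) &
                      meta$eye_id %in% lab$eye_id)
  bmeta <- meta[base_idx, ]
  y <- lab$progressing[match(bmeta$eye_id, lab$eye_id)]
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("predict_progression_from_baseline: need at least 2 eyes per label class")
  scalar_col <- c(cprnflt = "mean_cprnflt", sap_md = "sap_md",
                  fdt_md = "fdt_md")
  prob <- rep(NA_real_, length(y))
  for (pid in unique(bmeta$participant_id)) {
    test <- bmeta$participant_id == pid
    train <- !test
    if (length(unique(y[train])) < 2L)
      stop("predict_progression_from_baseline: a fold lost one label class")
    if (model == "pca") {
      # features are learned on all training participants' scans (all
      # visits), but the progression classifier sees baseline weights only
      tr_scan <- meta$participant_id %in% bmeta$participant_id[train]
      std <- fit_standardization(registered$X[tr_scan, , drop = FALSE])
      pca <- fit_rnfl_pca(
        apply_standardization(registered$X[tr_scan, , drop = FALSE], std),
        K = K, map_dim = registered$map_dim)
      Wtr <- project_weights(
        apply_standardization(registered$X[base_idx[train], , drop = FALSE], std), pca)
      Wte <- project_weights(
        apply_standardization(registered$X[base_idx[test], , drop = FALSE], std), pca)
      sc <- fit_logistic_scorer(Wtr, y[train])
      prob[test] <- sc$predict(Wte)
    } else {
      xcol <- scalar_col[[model]]
      sc <- fit_logistic_scorer(matrix(bmeta[[xcol]][train], ncol = 1L),
                                y[train])
      prob[test] <- sc$predict(matrix(bmeta[[xcol]][test], ncol = 1L))
    }
  }
  scores <- data.frame(eye_id = bmeta$eye_id,
                       participant_id = bmeta$participant_id,
                       age = bmeta$age, progressing = y, prob = prob,
                       model = model, stringsAsFactors = FALSE)
  # resampling unit: participant within label, so a participant whose two
  # eyes carry different labels contributes each eye to its own stratum
  # while same-label eyes stay clustered
  unit <- paste(scores$participant_id, scores$progressing)
  ev <- age_controlled_bootstrap_auc(scores$prob, scores$progressing,
                                     scores$age, unit,
                                     n_boot = n_boot, seed = seed,
                                     bin_width = bin_width)
  structure(list(scores = scores, auc = ev, model = model, K = K),
            class = "progression_prediction")
}
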