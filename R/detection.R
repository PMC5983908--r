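#' Mann-Whitney AUC
#'
#' Area under the ROC curve computed in its rank (Mann-Whitney) form:
#' the probability that a randomly chosen case scores higher than a
#' randomly chosen control, counting ties as one half. Identical to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels logical (or coercible) case indicator.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("auc_mw: both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve coordinates
#'
#' @inheritParams auc_mw
#' @return Data frame of `fpr`, `tpr`, and `threshold`, ordered for plotting.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  uniq <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(l)[uniq]; fp <- cumsum(!l)[uniq]
  data.frame(threshold = c(Inf, s[uniq]),
             tpr = c(0, tp / sum(l)), fpr = c(0, fp / sum(!l)))
}

# Ridge-penalized logistic regression by IRLS (intercept unpenalized).
# Used as a stabilized fallback when plain ML fitting fails to converge
# or separates.
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 100L, tol = 1e-8) {
  X <- cbind(1, as.matrix(X))
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / wt
    A <- crossprod(X * wt, X) + pen
    bnew <- drop(solve(A, crossprod(X * wt, z)))
    if (max(abs(bnew - beta)) < tol) { beta <- bnew; break }
    beta <- bnew
  }
  beta
}

# Fit a logistic model on a predictor matrix and return a scoring
# function; falls back to ridge IRLS on non-convergence/separation.
fit_logistic_scorer <- function(X, y) {
  X <- as.matrix(X)
  df <- data.frame(y = as.numeric(y), X)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged) {
    beta <- ridge_logistic(X, as.numeric(y))
    list(predict = function(Xn) stats::plogis(drop(cbind(1, as.matrix(Xn)) %*% beta)),
         flagged = TRUE)
  } else {
    list(predict = function(Xn) {
      nd <- data.frame(as.matrix(Xn))
      names(nd) <- names(df)[-1L]
      unname(stats::predict(fit, newdata = nd, type = "response"))
    }, flagged = FALSE)
  }
}

#' Participant-based leave-one-out glaucoma detection scores
#'
#' For each participant in turn, all of that participant's scans are
#' removed; the per-pixel standardization, the PCA feature model (first
#' `K` components), and a logistic model predicting the probability that
#' a thickness map comes from a glaucoma eye are fit on the remaining
#' participants' scans; held-out scans are then scored. Comparator models
#' (mean cpRNFL thickness, SAP MD, FDT MD as single predictors) are fit
#' under the identical fold structure so all AUC comparisons share one
#' harness.
#'
#' @param registered a `registered_cohort`.
#' @param K number of PCA features for the map-based model.
#' @param models character subset of
#'   `c("pca", "cprnflt", "sap_md", "fdt_md")`.
#' @return Data frame of class `loo_predictions`: one row per scan and
#'   model with the held-out probability of glaucoma, plus `ridge_flagged`
#'   marking folds refit with the stabilized solver.
#' @export
loo_scores <- function(registered, K = 10L,
                       models = c("pca", "cprnflt", "sap_md", "fdt_md")) {
  stopifnot(inherits(registered, "registered_cohort"))
  models <- match.arg(models, several.ok = TRUE)
  meta <- registered$meta
  label <- meta$group == "glaucoma"
  pids <- unique(meta$participant_id)
  if (length(unique(meta$participant_id[label])) < 2L ||
      length(unique(meta$participant_id[!label])) < 2L)
    stop("loo_scores: need at least 2 participants per class")
  scalar_col <- c(cprnflt = "mean_cprnflt", sap_md = "sap_md",
                  fdt_md = "fdt_md")
  out <- list()
  for (pid in pids) {
    test <- meta$participant_id == pid
    train <- !test
    for (mod in models) {
      if (mod == "pca") {
        std <- fit_standardization(registered$X[train, , drop = FALSE])
        Ztr <- apply_standardization(registered$X[train, , drop = FALSE], std)
        pca <- fit_rnfl_pca(Ztr, K = K, map_dim = registered$map_dim)
        Wtr <- project_weights(Ztr, pca)
        Wte <- project_weights(
          apply_standardization(registered$X[test, , drop = FALSE], std), pca)
        sc <- fit_logistic_scorer(Wtr, label[train])
        prob <- sc$predict(Wte)
      } else {
        xcol <- scalar_col[[mod]]
        # logistic fit learns the sign, so AUC matches the raw measurement
        sc <- fit_logistic_scorer(matrix(meta[[xcol]][train], ncol = 1L),
                                  label[train])
        prob <- sc$predict(matrix(meta[[xcol]][test], ncol = 1L))
      }
      out[[length(out) + 1L]] <- data.frame(
        scan_id = meta$scan_id[test], participant_id = pid,
        eye_id = meta$eye_id[test], visit_month = meta$visit_month[test],
        label = label[test], age = meta$age[test], model = mod,
        prob = prob, ridge_flagged = sc$flagged, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("loo_predictions", class(out))
  out
}

# Participant-level table and age-matching control weights used by the
# age-controlled bootstrap. Controls are reweighted so their age-bin
# distribution matches the cases'; bins holding cases but no controls are
# merged with the nearest control-occupied bin.
age_control_weights <- function(age, label, bin_width = 5) {
  breaks <- seq(floor(min(age) / bin_width) * bin_width,
                ceiling((max(age) + 1e-9) / bin_width) * bin_width,
                by = bin_width)
  bin <- findInterval(age, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  case_n <- tabulate(bin[label], nb)
  ctrl_n <- tabulate(bin[!label], nb)
  merged <- FALSE
  for (b in which(case_n > 0L & ctrl_n == 0L)) {
    cand <- which(ctrl_n > 0L)
    tgt <- cand[which.min(abs(cand - b))]
    case_n[tgt] <- case_n[tgt] + case_n[b]
    case_n[b] <- 0L
    merged <- TRUE
  }
  wbin <- ifelse(ctrl_n > 0L, (case_n / sum(case_n)) / (ctrl_n / sum(ctrl_n)), 0)
  w <- rep(1, length(age))
  w[!label] <- wbin[bin[!label]]
  if (all(w[!label] == 0)) w[!label] <- 1  # degenerate: no overlap at all
  list(weights = w, merged = merged)
}

boot_resample_indices <- function(part, n_boot) {
  case_ids <- which(part$label)
  ctrl_ids <- which(!part$label)
  wctrl <- part$weight[ctrl_ids]
  lapply(seq_len(n_boot), function(b) {
    c(sample(case_ids, length(case_ids), replace = TRUE),
      sample(ctrl_ids, length(ctrl_ids), replace = TRUE,
             prob = if (sum(wctrl) > 0) wctrl else NULL))
  })
}

# Shared machinery: participant table + replicate AUCs for one or two
# score vectors under identical age-controlled resamples.
boot_auc_engine <- function(scores_list, labels, ages, participant,
                            n_boot, seed, bin_width) {
  stopifnot(n_boot >= 200L)
  if (is.null(participant)) participant <- seq_along(labels)
  labels <- as.logical(labels)
  df <- data.frame(participant = participant, label = labels, age = ages)
  part <- unique(df[c("participant", "label", "age")])
  if (any(duplicated(part$participant)))
    stop("age-controlled bootstrap: inconsistent label/age within participant")
  aw <- age_control_weights(part$age, part$label, bin_width)
  part$weight <- aw$weights
  row_of_part <- split(seq_along(labels), match(participant, part$participant))
  with_seed(seed, {
    idx <- boot_resample_indices(part, n_boot)
    reps <- vapply(idx, function(ii) {
      rows <- unlist(row_of_part[ii], use.names = FALSE)
      vapply(scores_list, function(s) auc_mw(s[rows], labels[rows]),
             numeric(1))
    }, numeric(length(scores_list)))
  })
  list(reps = if (is.matrix(reps)) reps else matrix(reps, nrow = 1L),
       merged_bins = aw$merged)
}

#' Age-controlled bootstrap AUC
#'
#' Estimates an AUC while controlling for an age difference between cases
#' and controls: bootstrap replicates resample participants (not eyes or
#' scans, respecting within-participant clustering), drawing controls
#' with weights that reweight the control age distribution onto the case
#' age distribution (frequency ratios over 5-year age bins). The AUC is
#' averaged over replicates with a percentile confidence interval.
#'
#' @param scores,labels scan-level scores and case indicators.
#' @param ages age per scan (constant within participant).
#' @param participant participant id per scan (resampling unit); default
#'   treats every scan as its own participant.
#' @param n_boot number of bootstrap replicates (>= 200).
#' @param seed integer seed; mandatory for reproducibility.
#' @param bin_width age bin width in years.
#' @param conf confidence level of the percentile interval.
#' @return List of class `boot_auc`: `auc` (bootstrap mean), `ci`,
#'   `naive_auc` (plain full-sample AUC), `n_boot`, `seed`,
#'   `merged_bins` flag.
#' @export
age_controlled_bootstrap_auc <- function(scores, labels, ages,
                                         participant = NULL, n_boot = 2000L,
                                         seed, bin_width = 5, conf = 0.95) {
  stopifnot(all(is.finite(ages)))
  eng <- boot_auc_engine(list(scores), labels, ages, participant,
                         n_boot, seed, bin_width)
  reps <- eng$reps[1L, ]
  a <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  structure(list(auc = mean(reps),
                 ci = unname(stats::quantile(reps, a)),
                 naive_auc = auc_mw(scores, as.logical(labels)),
                 reps = reps, n_boot = n_boot, seed = seed,
                 merged_bins = eng$merged_bins),
            class = "boot_auc")
}

#' @export
print.boot_auc <- function(x, ...) {
  cat(sprintf("age-controlled bootstrap AUC: %.3f (CI %.3f-%.3f; naive %.3f; %d replicates)\n",
              x$auc, x$ci[1L], x$ci[2L], x$naive_auc, x$n_boot))
  invisible(x)
}

#' Paired age-controlled bootstrap comparison of two AUCs
#'
#' Both score vectors are evaluated on identical age-controlled
#' participant resamples; the two-sided p-value comes from the bootstrap
#' distribution of the AUC difference.
#'
#' @param scores_a,scores_b paired scan-level scores on the same rows.
#' @inheritParams age_controlled_bootstrap_auc
#' @return List of class `auc_comparison`: `auc_a`, `auc_b`, `delta`,
#'   `p`, `ci_delta`, `n_boot`, `seed`.
#' @export
compare_auc <- function(scores_a, scores_b, labels, ages, participant = NULL,
                        n_boot = 2000L, seed, bin_width = 5) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  eng <- boot_auc_engine(list(scores_a, scores_b), labels, ages, participant,
                         n_boot, seed, bin_width)
  d <- eng$reps[1L, ] - eng$reps[2L, ]
  p <- 2 * min((sum(d <= 0) + 1) / (n_boot + 1),
               (sum(d >= 0) + 1) / (n_boot + 1))
  structure(list(auc_a = mean(eng$reps[1L, ]), auc_b = mean(eng$reps[2L, ]),
                 delta = mean(d), p = min(p, 1),
                 ci_delta = unname(stats::quantile(d, c(0.025, 0.975))),
                 n_boot = n_boot, seed = seed),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("AUC comparison: %.3f vs %.3f (delta %+.3f, P = %.3g, %d paired replicates)\n",
              x$auc_a, x$auc_b, x$delta, x$p, x$n_boot))
  invisible(x)
}
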