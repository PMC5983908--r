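#' Age-adjusted univariate association between a feature and a measurement
#'
#' Ordinary least squares of the clinical measurement on one RNFL PCA
#' feature weight with age as a covariate; a significant regression slope
#' for the feature indicates an association. Age is included in every
#' model because the diagnostic groups differ in age by design.
#'
#' @param w feature weight vector (one value per eye/scan).
#' @param y quantitative measurement, aligned with `w`.
#' @param age age covariate, years.
#' @param feature,measurement optional labels carried into the result.
#' @return A one-row data frame of class `association_result`: slope,
#'   standard error, t, p-value, model R-squared, n, and a `flagged`
#'   column set when the predictor is constant/collinear (p undefined).
#' @export
univariate_feature_test <- function(w, y, age, feature = NA, measurement = NA) {
  cc <- stats::complete.cases(w, y, age)
  w <- w[cc]; y <- y[cc]; age <- age[cc]
  n <- length(y)
  if (n < 4L) stop("univariate_feature_test: need at least 4 complete cases")
  out <- data.frame(feature = feature, measurement = measurement,
                    slope = NA_real_, se = NA_real_, t = NA_real_,
                    p = NA_real_, r2 = NA_real_, n = n, flagged = FALSE,
                    stringsAsFactors = FALSE)
  fit <- stats::lm(y ~ w + age)
  if (stats::sd(w) == 0 || any(!is.finite(stats::coef(fit))) ||
      fit$qr$rank < 3L) {
    out$flagged <- TRUE
    class(out) <- c("association_result", class(out))
    return(out)
  }
  sm <- summary(fit)
  co <- sm$coefficients["w", ]
  out$slope <- co[["Estimate"]]; out$se <- co[["Std. Error"]]
  out$t <- co[["t value"]]; out$p <- co[["Pr(>|t|)"]]
  out$r2 <- sm$r.squared
  class(out) <- c("association_result", class(out))
  out
}

#' Age-adjusted one-way ANOVA of a feature across categories
#'
#' Age is regressed out of the feature weights first; the residuals are
#' then compared across categories with a single-factor ANOVA.
#'
#' @param w feature weight vector.
#' @param category factor (or coercible) with at least 2 non-empty levels,
#'   each with at least 2 members.
#' @param age age covariate, years.
#' @inheritParams univariate_feature_test
#' @return A one-row data frame with the F statistic in `slope`-free
#'   columns `F` and `p`.
#' @export
categorical_test <- function(w, category, age, feature = NA, measurement = NA) {
  category <- droplevels(as.factor(category))
  cc <- stats::complete.cases(w, category, age)
  w <- w[cc]; category <- droplevels(category[cc]); age <- age[cc]
  if (nlevels(category) < 2L)
    stop("categorical_test: need at least 2 non-empty categories")
  if (any(table(category) < 2L))
    stop("categorical_test: every category needs at least 2 members")
  resid_w <- stats::residuals(stats::lm(w ~ age))
  an <- stats::anova(stats::lm(resid_w ~ category))
  data.frame(feature = feature, measurement = measurement,
             F = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
             n = length(w), df1 = an[["Df"]][1L], df2 = an[["Df"]][2L],
             stringsAsFactors = FALSE)
}

#' Bonferroni significance flags
#'
#' @param pvals vector of p-values.
#' @param alpha familywise error level in (0, 1).
#' @param m family size (>= number of p-values); the effective per-test
#'   threshold is `alpha / m`.
#' @return Logical vector: `p < alpha / m`.
#' @export
bonferroni <- function(pvals, alpha = 0.05, m = length(pvals)) {
  if (alpha <= 0 || alpha >= 1) stop("bonferroni: alpha must be in (0, 1)")
  if (m < length(pvals)) stop("bonferroni: family size m smaller than the number of tests")
  pvals < alpha / m
}

#' Variance in a measurement explained by the full feature set
#'
#' OLS of the measurement on all `K` feature weights plus age; returns the
#' coefficient of determination and fitted values (for predicted-versus-
#' observed scatterplots).
#'
#' @param W `n x K` weight matrix.
#' @param y quantitative measurement.
#' @param age age covariate.
#' @return List: `r2`, `fitted`, `observed`, overall-F `p`, `n`, `rank_deficient`.
#' @export
multivariate_r2 <- function(W, y, age) {
  W <- as.matrix(W)
  cc <- stats::complete.cases(W, y, age)
  W <- W[cc, , drop = FALSE]; y <- y[cc]; age <- age[cc]
  n <- length(y); K <- ncol(W)
  if (n <= K + 2L) stop("multivariate_r2: need n > K + 2 complete cases")
  fit <- stats::lm(y ~ W + age)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(r2 = sm$r.squared,
       fitted = unname(stats::fitted(fit)), observed = y,
       p = if (!is.null(fstat))
         stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
       else NA_real_,
       n = n,
       rank_deficient = fit$qr$rank < K + 2L)
}

#' Feature-measurement association table
#'
#' Runs the per-feature association battery over a set of quantitative
#' measurements (univariate regression) and categorical variables
#' (ANOVA), all age-adjusted, and applies a Bonferroni correction with
#' family size `m = features x measurements` (declared in the output).
#'
#' @param W `n x K` matrix of feature weights (typically baseline scans).
#' @param data data frame aligned with `W` containing `age`, the
#'   quantitative columns in `quantitative`, and the categorical columns
#'   in `categorical`.
#' @param quantitative,categorical character vectors of column names.
#' @param alpha familywise error level.
#' @return Data frame with one row per feature-measurement pair, p-values,
#'   Bonferroni flags, and attributes `family_size` and `alpha`.
#' @export
association_table <- function(W, data,
                              quantitative = c("sap_md", "sap_psd", "fdt_md",
                                               "fdt_psd", "mean_cprnflt"),
                              categorical = c("group", "sex"),
                              alpha = 0.05) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == nrow(data), "age" %in% names(data))
  K <- ncol(W)
  rows <- list()
  for (k in seq_len(K)) {
    for (msr in quantitative) {
      r <- univariate_feature_test(W[, k], data[[msr]], data$age,
                                   feature = k, measurement = msr)
      rows[[length(rows) + 1L]] <-
        data.frame(feature = k, measurement = msr, kind = "linear",
                   estimate = r$slope, statistic = r$t, p = r$p,
                   stringsAsFactors = FALSE)
    }
    for (msr in categorical) {
      r <- categorical_test(W[, k], data[[msr]], data$age,
                            feature = k, measurement = msr)
      rows[[length(rows) + 1L]] <-
        data.frame(feature = k, measurement = msr, kind = "anova",
                   estimate = NA_real_, statistic = r$F, p = r$p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$significant <- bonferroni(out$p, alpha = alpha, m = m)
  attr(out, "family_size") <- m
  attr(out, "alpha") <- alpha
  out
}
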