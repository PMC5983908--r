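test_that("noiseless linear relation gives the exact slope with tiny p", {
  withr::with_seed(41, {
    w <- rnorm(40); age <- rnorm(40, 60, 8)
  })
  r <- univariate_feature_test(w, 3 * w, age)
  expect_equal(r$slope, 3, tolerance = 1e-8)
  expect_lt(r$p, 1e-12)
})

test_that("coefficients match a hand-rolled normal-equations solver", {
  withr::with_seed(42, {
    w <- rnorm(30); age <- rnorm(30, 60, 10)
    y <- 1.5 + 0.8 * w - 0.05 * age + rnorm(30)
  })
  r <- univariate_feature_test(w, y, age)
  X <- cbind(1, w, age)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_lt(abs(r$slope - beta[2]), 1e-10)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (30 - 3)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_lt(abs(r$se - se), 1e-10)
})

test_that("type-I error of the age-adjusted slope test is near nominal under the null", {
  withr::with_seed(43, {
    n <- 40; reps <- 1000
    rej <- vapply(seq_len(reps), function(i) {
      age <- rnorm(n, 60, 8)
      y <- 0.5 * age + rnorm(n)       # pure age effect
      w <- rnorm(n)                   # independent feature
      univariate_feature_test(w, y, age)$p < 0.05
    }, logical(1))
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.075)
})

test_that("constant predictor is flagged rather than tested", {
  withr::with_seed(44, {
    age <- rnorm(20, 60, 8); y <- rnorm(20)
  })
  r <- univariate_feature_test(rep(1, 20), y, age)
  expect_true(r$flagged)
  expect_true(is.na(r$p))
})

test_that("ANOVA on age-adjusted residuals behaves across separations", {
  withr::with_seed(45, {
    age <- rnorm(60, 60, 8)
    g <- rep(c("a", "b"), each = 30)
    w_null <- 0.1 * age + rnorm(60)
    w_sep <- w_null + ifelse(g == "a", 0, 10)
  })
  expect_gt(categorical_test(w_null, g, age)$p, 0.001)
  expect_lt(categorical_test(w_sep, g, age)$p, 1e-6)
  expect_error(categorical_test(w_null, rep("a", 60), age), "categories")
  expect_error(categorical_test(w_null[1:3], c("a", "a", "b"), age[1:3]),
               "members")
})

test_that("bonferroni thresholds at alpha over the family size", {
  expect_true(bonferroni(0.04, m = 1))
  expect_false(bonferroni(0.04, m = 10))
  expect_true(all(bonferroni(rep(0, 5), m = 50)))
  expect_error(bonferroni(0.5, alpha = 1.2), "alpha")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "family")
})

test_that("multivariate R2: exact fit, overfit floor, rank flag", {
  withr::with_seed(46, {
    W <- matrix(rnorm(60 * 5), 60, 5)
    age <- rnorm(60, 60, 8)
  })
  y_exact <- drop(W %*% c(1, -2, 0.5, 0, 3))
  expect_equal(multivariate_r2(W, y_exact, age)$r2, 1, tolerance = 1e-10)
  # independent noise: E[R2] around (K+1)/(n-1)
  withr::with_seed(47, {
    r2s <- vapply(1:200, function(i) {
      Wn <- matrix(rnorm(60 * 5), 60, 5)
      multivariate_r2(Wn, rnorm(60), rnorm(60, 60, 8))$r2
    }, numeric(1))
  })
  expect_lt(abs(mean(r2s) - 6 / 59), 0.015)
  # duplicated column flags rank deficiency
  Wd <- cbind(W, W[, 1])
  expect_true(multivariate_r2(Wd, y_exact, age)$rank_deficient)
})

test_that("adding a predictor never lowers in-sample R2", {
  withr::with_seed(48, {
    W <- matrix(rnorm(50 * 8), 50, 8)
    age <- rnorm(50, 60, 8)
    y <- drop(W[, 1:3] %*% c(1, 1, 1)) + rnorm(50)
  })
  r2 <- vapply(2:8, function(k) multivariate_r2(W[, 1:k], y, age)$r2, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("cohort-level R2 agrees with the generator's signal-to-noise ratio", {
  gen <- stats_cohort(key = "stats_cohort")
  reg <- stats_registered()
  std <- fit_standardization(reg$X)
  pca <- fit_rnfl_pca(apply_standardization(reg$X, std), K = 10L)
  b <- reg$meta$visit_month == 0
  W <- project_weights(apply_standardization(reg$X[b, , drop = FALSE], std), pca)
  r2 <- multivariate_r2(W, reg$meta$sap_md[b], reg$meta$age[b])$r2
  cfg <- gen$cohort$config
  eyes <- gen$truth$eyes
  sig <- var(cfg$sap_md_link * eyes$baseline_deficit)
  implied <- sig / (sig + cfg$functional_noise_sd^2)
  expect_lt(abs(r2 - implied), 0.1)
})

test_that("association table flags the designed structure-function links", {
  reg <- stats_registered()
  std <- fit_standardization(reg$X)
  pca <- fit_rnfl_pca(apply_standardization(reg$X, std), K = 6L)
  b <- reg$meta$visit_month == 0
  W <- project_weights(apply_standardization(reg$X[b, , drop = FALSE], std), pca)
  tab <- association_table(W, reg$meta[b, ])
  expect_equal(nrow(tab), 6L * 7L)
  expect_equal(attr(tab, "family_size"), 42L)
  # the designed structural link survives Bonferroni; the group contrast
  # shows at least a nominal association after age adjustment (age and
  # group are confounded by design, which costs power)
  expect_true(any(tab$significant[tab$measurement == "mean_cprnflt"]))
  expect_lt(min(tab$p[tab$measurement == "group"]), 0.05)
})
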