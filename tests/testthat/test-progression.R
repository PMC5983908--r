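sim_healthy_visits <- function(n_part = 28L, mean_slope = -0.4,
                               sd_p = 0.5, sd_e = 0.35,
                               off_p = 4, off_e = 3, noise = 0.3,
                               n_visits = 9L) {
  rows <- list()
  for (p in seq_len(n_part)) {
    sp <- rnorm(1, 0, sd_p); op <- rnorm(1, 0, off_p)
    for (ei in 1:2) {
      se <- rnorm(1, 0, sd_e); oe <- rnorm(1, 0, off_e)
      months <- seq(0, 24, length.out = n_visits)
      y <- 100 + op + oe + (mean_slope + sp + se) * months / 12 +
        rnorm(n_visits, 0, noise)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = sprintf("P%02d", p),
        eye_id = sprintf("P%02d_E%d", p, ei),
        visit_month = months, mean_cprnflt = y,
        true_slope = mean_slope + sp + se)
    }
  }
  do.call(rbind, rows)
}

test_that("eye-level OLS rates: exact line, flat series, normal-equations oracle", {
  months <- seq(0, 24, by = 3)
  r <- eye_rate_ols(months, 100 - 1.5 * months / 12)
  expect_equal(r$slope, -1.5, tolerance = 1e-10)
  expect_lt(r$p, 1e-10)
  flat <- eye_rate_ols(months, rep(95, 9))
  expect_equal(flat$slope, 0)
  expect_equal(flat$p, 1)
  withr::with_seed(61, y <- 100 - 0.8 * months / 12 + rnorm(9, 0, 0.3))
  r2 <- eye_rate_ols(months, y)
  X <- cbind(1, months / 12)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_lt(abs(r2$slope - beta[2]), 1e-10)
  expect_error(eye_rate_ols(c(0, 3), c(1, 2)), "3 visits")
})

test_that("zero-noise common slope collapses the healthy distribution onto it", {
  d <- sim_healthy_visits(n_part = 8L, mean_slope = -0.2, sd_p = 0, sd_e = 0,
                          off_p = 0, off_e = 0, noise = 0)
  dist <- fit_healthy_rate_distribution(d, "mean_cprnflt", min_eyes = 10L)
  expect_lt(max(abs(dist$slopes + 0.2)), 1e-6)
  expect_equal(dist$threshold, -0.2, tolerance = 1e-6)
})

test_that("mixed model recovers slope variance components from the generator design", {
  withr::with_seed(62, {
    vps <- c(); ves <- c()
    for (i in 1:15) {
      d <- sim_healthy_visits()
      fit <- suppressMessages(lme4::lmer(
        mean_cprnflt ~ I(visit_month / 12) + (I(visit_month / 12) | participant_id) +
          (I(visit_month / 12) | eye_id), data = d, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore",
                                    calc.derivs = FALSE)))
      vc <- as.data.frame(lme4::VarCorr(fit))
      pick <- function(g) vc$sdcor[vc$grp == g & !is.na(vc$var1) &
                                     vc$var1 != "(Intercept)" & is.na(vc$var2)]
      vps <- c(vps, pick("participant_id")); ves <- c(ves, pick("eye_id"))
    }
  })
  expect_lt(abs(mean(vps^2) - 0.5^2) / 0.5^2, 0.5)
  expect_lt(abs(mean(ves^2) - 0.35^2) / 0.35^2, 0.5)
})

test_that("per-eye mixed-model slopes track the simulated true rates", {
  withr::with_seed(63, d <- sim_healthy_visits())
  dist <- fit_healthy_rate_distribution(d, "mean_cprnflt")
  truth <- d$true_slope[match(names(dist$slopes), d$eye_id)]
  expect_gt(cor(dist$slopes, truth), 0.6)
  expect_lt(mean(abs(dist$slopes - truth)), 0.25)
})

test_that("progression criterion combines the percentile and significance arms", {
  dist <- structure(list(measurement = "mean_cprnflt",
                         slopes = seq(-0.8, 0.2, length.out = 20),
                         threshold = -0.7, worse_direction = -1,
                         percentile = 0.95, fixed_slope = -0.3,
                         fixed_slope_se = 0.05, method = "lmm",
                         singular = FALSE, n_eyes = 20L),
                    class = "healthy_rate_dist")
  rates <- data.frame(eye_id = c("a", "b", "c", "d"),
                      slope = c(-1.2, -1.2, -0.3, -0.71),
                      p = c(0.01, 0.20, 0.01, 0.04))
  lab <- classify_progression(rates, dist)
  expect_equal(lab$progressing, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(lab$label, c("progressing", "stable", "stable", "progressing"))
})

test_that("labeled progression in a generated cohort reflects the true progressors", {
  gen <- stats_cohort(key = "stats_cohort")
  reg <- stats_registered()
  pl <- progression_labels(reg$meta, "mean_cprnflt")
  truth <- gen$truth$eyes
  tp <- truth$progressing[match(pl$labels$eye_id, truth$eye_id)]
  # specificity among truly-stable glaucoma eyes
  expect_lt(mean(pl$labels$progressing[!tp]), 0.15)
  # the labels carry real signal: true progressors are flagged far more
  # often than truly-stable eyes
  expect_gt(mean(pl$labels$progressing[tp]),
            mean(pl$labels$progressing[!tp]) + 0.2)
})

test_that("labeled fraction grows with the true progression slope magnitude", {
  frac <- vapply(c(-1.2, -2.5, -4.5), function(sl) {
    gen <- stats_cohort(n_g = 16L, n_h = 12L, seed = 64L,
                        progression_slope_mean = sl,
                        progression_slope_sd = 0.3)
    pl <- progression_labels(gen$cohort$meta, "mean_cprnflt")
    pl$counts[["progressing"]] / nrow(pl$labels)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
})

test_that("baseline progression prediction refuses degenerate label sets", {
  reg <- stats_registered()
  lab <- data.frame(eye_id = unique(reg$meta$eye_id[reg$meta$group == "glaucoma"]))
  lab$progressing <- FALSE
  lab$progressing[1] <- TRUE
  expect_error(predict_progression_from_baseline(reg, lab, model = "cprnflt",
                                                 n_boot = 200L, seed = 1),
               "2 eyes per label class")
})
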