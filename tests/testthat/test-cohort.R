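test_that("forced eye totals reproduce the study's 179 + 56 eyes from 93 + 28 participants", {
  cfg <- cohort_config(n_visits = 1L, grid_h = 60L, grid_w = 80L, seed = 9L)
  gen <- generate_cohort(cfg)
  eyes <- gen$truth$eyes
  expect_equal(sum(eyes$group == "glaucoma"), 179L)
  expect_equal(sum(eyes$group == "healthy"), 56L)
  expect_equal(length(unique(eyes$participant_id[eyes$group == "glaucoma"])), 93L)
  expect_equal(length(unique(eyes$participant_id[eyes$group == "healthy"])), 28L)
  # group difference at baseline plus the built-in age confound
  m <- gen$cohort$meta
  expect_lt(mean(m$mean_cprnflt[m$group == "glaucoma"]),
            mean(m$mean_cprnflt[m$group == "healthy"]))
  expect_gt(mean(m$age[m$group == "glaucoma"]),
            mean(m$age[m$group == "healthy"]))
})

test_that("no-variation configuration yields identical visit maps", {
  cfg <- cohort_config(n_glaucoma_participants = 2L, n_healthy_participants = 2L,
                       eye_totals = NULL, grid_h = 60L, grid_w = 80L,
                       n_visits = 3L, noise_sd = 0,
                       healthy_slope_mean = 0, slope_sd_participant = 0,
                       slope_sd_eye = 0, progressing_fraction = 0,
                       misalign_translation_px = 0, misalign_rotation_deg = 0,
                       misalign_scale = 0, landmark_noise_px = 0, seed = 4L)
  gen <- generate_cohort(cfg)
  for (e in unique(gen$cohort$meta$eye_id)) {
    ids <- gen$cohort$meta$scan_id[gen$cohort$meta$eye_id == e]
    v0 <- gen$cohort$maps[[ids[1]]]$values
    for (id in ids[-1]) expect_equal(gen$cohort$maps[[id]]$values, v0)
  }
})

test_that("a fixed seed reproduces the cohort bit-identically", {
  cfg <- cohort_config(n_glaucoma_participants = 3L, n_healthy_participants = 2L,
                       eye_totals = NULL, grid_h = 60L, grid_w = 80L,
                       n_visits = 2L, seed = 77L)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort$meta, g2$cohort$meta)
  expect_identical(lapply(g1$cohort$maps, `[[`, "values"),
                   lapply(g2$cohort$maps, `[[`, "values"))
  expect_identical(g1$truth$eyes, g2$truth$eyes)
})

test_that("per-eye OLS slopes of mean cpRNFL thickness recover the true rates", {
  gen <- stats_cohort(key = "stats_cohort")
  meta <- gen$cohort$meta
  eyes <- gen$truth$eyes
  err <- vapply(eyes$eye_id, function(e) {
    d <- meta[meta$eye_id == e, ]
    est <- eye_rate_ols(d$visit_month, d$mean_cprnflt)$slope
    abs(est - eyes$cprnflt_slope_true[eyes$eye_id == e])
  }, numeric(1))
  expect_lt(mean(err), 0.5)
})

test_that("progressing fraction and structure-function link match the design", {
  gen <- stats_cohort(key = "stats_cohort")
  eyes <- gen$truth$eyes
  g <- eyes[eyes$group == "glaucoma", ]
  # binomial interval around the configured progressing fraction
  pf <- gen$cohort$config$progressing_fraction
  ci <- qbinom(c(0.005, 0.995), nrow(g), pf)
  expect_gte(sum(g$progressing), ci[1])
  expect_lte(sum(g$progressing), ci[2])
  # healthy eyes carry no structural damage
  expect_true(all(eyes$severity[eyes$group == "healthy"] == 0))
  expect_true(all(!eyes$progressing[eyes$group == "healthy"]))
  # functional-structural link at baseline
  m0 <- gen$cohort$meta[gen$cohort$meta$visit_month == 0, ]
  d0 <- eyes$baseline_deficit[match(m0$eye_id, eyes$eye_id)]
  expect_gt(cor(-m0$sap_md, d0), 0.6)
})

test_that("laterality mix and misalignment metadata are recorded per scan", {
  gen <- small_cohort()
  eyes <- gen$truth$eyes
  expect_true(all(c("OD", "OS") %in% eyes$laterality))
  sc <- gen$truth$scans
  expect_true(all(abs(sc$mis_tx) <= gen$cohort$config$misalign_translation_px))
  expect_true(all(abs(sc$mis_theta) <=
                    gen$cohort$config$misalign_rotation_deg * pi / 180 + 1e-12))
  # OS scans have the ONH temporal->nasal order mirrored
  m <- gen$cohort$maps[[sc$scan_id[1]]]
  expect_true(m$orientation %in% c("OD", "OS"))
})

test_that("inconsistent configurations are rejected", {
  expect_error(cohort_config(progressing_fraction = 1.5, seed = 1))
  expect_error(cohort_config(seed = NULL), "seed")
  expect_error(cohort_config(grid_h = 100L, grid_w = 100L, seed = 1),
               "isotropic")
})
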