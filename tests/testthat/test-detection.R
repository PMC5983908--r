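test_that("Mann-Whitney AUC equals exhaustive pair counting, with and without ties", {
  brute_auc <- function(s, l) {
    cs <- s[l]; ct <- s[!l]
    tot <- 0
    for (a in cs) tot <- tot + sum(a > ct) + 0.5 * sum(a == ct)
    tot / (length(cs) * length(ct))
  }
  withr::with_seed(51, {
    for (i in 1:100) {
      n <- 30L
      l <- c(rep(TRUE, 12), rep(FALSE, 18))
      s <- if (i %% 2 == 0) sample(1:6, n, replace = TRUE) + rbinom(n, 1, 0.5) * as.numeric(l)
           else rnorm(n, mean = as.numeric(l))
      expect_identical(auc_mw(s, l), brute_auc(s, l))
    }
  })
})

test_that("AUC edge cases and monotone-transform invariance", {
  l <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(auc_mw(c(6:10, 1:5), l), 1)
  expect_equal(auc_mw(rep(3, 10), l), 0.5)
  expect_error(auc_mw(1:5, rep(TRUE, 5)), "classes")
  withr::with_seed(52, s <- rnorm(10))
  expect_equal(auc_mw(s, l), auc_mw(exp(3 * s) + 2, l))
  # score negation flips the AUC
  expect_equal(auc_mw(-s, l), 1 - auc_mw(s, l))
})

test_that("ROC coordinates integrate to the Mann-Whitney AUC", {
  withr::with_seed(53, {
    s <- rnorm(40); l <- rbinom(40, 1, 0.5) == 1
  })
  rc <- roc_points(s, l)
  trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
  expect_equal(trap, auc_mw(s, l), tolerance = 1e-12)
})

test_that("participant-based LOO keeps held-out participants out of training", {
  reg <- small_registered()
  sc <- loo_scores(reg, K = 5L, models = c("pca", "cprnflt"))
  # every scan scored once per model
  expect_equal(nrow(sc), 2L * nrow(reg$meta))
  expect_setequal(sc$scan_id[sc$model == "pca"], reg$meta$scan_id)
  # structural guard: each row's fold excluded its own participant
  expect_true(all(sc$participant_id == reg$meta$participant_id[
    match(sc$scan_id, reg$meta$scan_id)]))
  # map-based model separates groups on this strong-signal fixture
  s <- sc[sc$model == "pca", ]
  expect_gt(auc_mw(s$prob, s$label), 0.9)
})

test_that("two perfectly separated participants rank correctly under LOO", {
  gen <- generate_cohort(cohort_config(
    n_glaucoma_participants = 2L, n_healthy_participants = 2L,
    eye_totals = NULL, grid_h = 60L, grid_w = 80L, n_visits = 2L,
    severity_shape = 40, severity_scale = 1.5,  # deep, consistent damage
    pattern_weights = c(inferior_arcuate = 0, superior_arcuate = 0,
                        diffuse_macular = 1),   # one shared damage mode
    noise_sd = 0, offset_sd_participant = 0, offset_sd_eye = 0,
    misalign_translation_px = 0, misalign_rotation_deg = 0,
    misalign_scale = 0, landmark_noise_px = 0, seed = 55L))
  reg <- register_cohort(gen$cohort, ecc_refine = FALSE)
  sc <- loo_scores(reg, K = 2L, models = "pca")
  expect_gt(min(sc$prob[sc$label]), max(sc$prob[!sc$label]))
})

test_that("age-controlled bootstrap is deterministic and matches the plain bootstrap without confounding", {
  withr::with_seed(56, {
    n <- 120
    label <- rep(c(TRUE, FALSE), each = 60)
    age <- rnorm(n, 60, 8)              # identical age distributions
    score <- rnorm(n) + 1.2 * label
  })
  b1 <- age_controlled_bootstrap_auc(score, label, age, n_boot = 400L, seed = 10)
  b2 <- age_controlled_bootstrap_auc(score, label, age, n_boot = 400L, seed = 10)
  expect_identical(b1$auc, b2$auc)
  expect_identical(b1$ci, b2$ci)
  expect_lt(abs(b1$auc - b1$naive_auc), 0.03)
})

test_that("age-controlled bootstrap removes a pure age confound", {
  withr::with_seed(57, {
    n <- 300
    label <- rep(c(TRUE, FALSE), c(150, 150))
    age <- ifelse(label, rnorm(n, 68, 7), rnorm(n, 50, 7))
    score <- age + rnorm(n, sd = 4)     # score carries age only
  })
  b <- age_controlled_bootstrap_auc(score, label, age, n_boot = 600L, seed = 11)
  expect_gt(b$naive_auc, 0.7)
  expect_lt(abs(b$auc - 0.5), 0.1)
})

test_that("paired AUC comparison: identity, symmetry, separable-vs-null power", {
  withr::with_seed(58, {
    n <- 200
    label <- rep(c(TRUE, FALSE), each = 100)
    age <- rnorm(n, 60, 8)
    good <- as.numeric(label) + rnorm(n, sd = 0.1)   # nearly perfect
    rand <- rnorm(n)                                  # uninformative
  })
  same <- compare_auc(good, good, label, age, n_boot = 300L, seed = 12)
  expect_equal(same$delta, 0)
  expect_gt(same$p, 0.9)
  cmp <- compare_auc(good, rand, label, age, n_boot = 500L, seed = 13)
  expect_lt(cmp$p, 0.01)
  rev <- compare_auc(rand, good, label, age, n_boot = 500L, seed = 13)
  expect_equal(rev$delta, -cmp$delta, tolerance = 1e-12)
  expect_equal(rev$p, cmp$p)
})

test_that("ridge fallback engages on separable data instead of failing", {
  withr::with_seed(59, {
    x <- c(rnorm(20, -3), rnorm(20, 3))
    y <- rep(c(0, 1), each = 20)
  })
  sc <- rnflpca:::fit_logistic_scorer(matrix(x, ncol = 1), y)
  expect_true(sc$flagged)
  p <- sc$predict(matrix(c(-4, 4), ncol = 1))
  expect_lt(p[1], 0.1); expect_gt(p[2], 0.9)
})
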