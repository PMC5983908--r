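# Shared fixtures, all generated in code and memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A smooth structured image for registration tests.
test_image <- function(h = 60L, w = 80L) {
  xg <- outer(rep(1, h), 0:(w - 1))
  yg <- outer(0:(h - 1), rep(1, w))
  100 * exp(-((xg - 0.4 * w)^2 + (yg - 0.45 * h)^2) / (0.02 * w * h)) +
    60 * exp(-((xg - 0.7 * w)^2 + (yg - 0.6 * h)^2) / (0.01 * w * h)) +
    20 * sin(xg / 7) * cos(yg / 9) + 40
}

# Small misaligned longitudinal cohort exercising the full chain.
small_cohort <- function() memo("small_cohort", {
  generate_cohort(cohort_config(
    n_glaucoma_participants = 8L, n_healthy_participants = 5L,
    eye_totals = NULL, grid_h = 60L, grid_w = 80L, n_visits = 4L,
    seed = 101L))
})

small_registered <- function() memo("small_registered", {
  register_cohort(small_cohort()$cohort)
})

# Aligned-by-construction cohort (no misalignment, exact landmarks) for
# statistical tests that do not probe registration.
stats_cohort <- function(n_g = 24L, n_h = 16L, n_visits = 9L, seed = 202L,
                         key = NULL, ...) {
  build <- function() generate_cohort(cohort_config(
    n_glaucoma_participants = n_g, n_healthy_participants = n_h,
    eye_totals = NULL, grid_h = 60L, grid_w = 80L, n_visits = n_visits,
    misalign_translation_px = 0, misalign_rotation_deg = 0,
    misalign_scale = 0, landmark_noise_px = 0, seed = seed, ...))
  if (is.null(key)) build() else memo(key, build())
}

stats_registered <- function() memo("stats_registered", {
  register_cohort(stats_cohort(key = "stats_cohort")$cohort,
                  ecc_refine = FALSE)
})

# Same-participant-leaking LOO variant: holds out one SCAN at a time,
# so the held-out participant's other (near-identical) scans remain in
# training, and the standardization/PCA are fit once on all scans.
# Exists only to demonstrate that the participant-level guard in
# loo_scores() matters.
loo_scores_leaky <- function(registered, K = 10L) {
  meta <- registered$meta
  label <- meta$group == "glaucoma"
  std <- fit_standardization(registered$X)
  Z <- apply_standardization(registered$X, std)
  pca <- fit_rnfl_pca(Z, K = K, map_dim = registered$map_dim)
  W <- project_weights(Z, pca)
  prob <- vapply(seq_along(label), function(i) {
    df <- data.frame(y = as.numeric(label[-i]), W[-i, , drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    nd <- data.frame(W[i, , drop = FALSE])
    names(nd) <- names(df)[-1L]
    unname(stats::predict(fit, newdata = nd, type = "response"))
  }, numeric(1))
  data.frame(scan_id = meta$scan_id, participant_id = meta$participant_id,
             label = label, age = meta$age, prob = prob,
             stringsAsFactors = FALSE)
}

# Relabel a cohort's groups by a participant-level permutation, keeping
# the class sizes; maps are untouched so labels carry no signal.
permute_cohort_labels <- function(registered, seed = 1L) {
  meta <- registered$meta
  part <- unique(meta[c("participant_id", "group")])
  perm <- withr::with_seed(seed, sample(part$group))
  meta$group <- perm[match(meta$participant_id, part$participant_id)]
  registered$meta <- meta
  registered
}
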