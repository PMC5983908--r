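test_that("components match a dense covariance eigendecomposition oracle", {
  withr::with_seed(31, Z <- matrix(rnorm(20 * 300), 20, 300))
  mdl <- fit_rnfl_pca(Z, K = 8L)
  eo <- eigen(cov(Z), symmetric = TRUE)
  tot <- sum(pmax(eo$values, 0))
  for (k in 1:8) {
    v <- eo$vectors[, k]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_lt(max(abs(v - mdl$components[k, ])), 1e-8)
    expect_lt(abs(mdl$variance_fraction[k] - eo$values[k] / tot), 1e-10)
  }
})

test_that("a rank-1 stack is explained entirely by its first component", {
  withr::with_seed(32, {
    pattern <- rnorm(150)
    amp <- rnorm(12, sd = 3)
  })
  Z <- outer(amp, pattern)
  mdl <- fit_rnfl_pca(Z, K = 1L)
  expect_equal(mdl$variance_fraction[1], 1, tolerance = 1e-12)
  u <- pattern / sqrt(sum(pattern^2))
  if (u[which.max(abs(u))] < 0) u <- -u
  expect_lt(max(abs(abs(mdl$components[1, ]) - abs(u))), 1e-8)
  expect_error(fit_rnfl_pca(Z, K = 2L), "rank")
})

test_that("model invariants hold: orthonormality, ordering, unit total variance", {
  withr::with_seed(33, Z <- matrix(rnorm(25 * 400), 25, 400))
  mdl <- fit_rnfl_pca(Z, K = 10L)
  G <- mdl$components %*% t(mdl$components)
  expect_lt(max(abs(G - diag(10))), 1e-8)
  expect_true(all(diff(mdl$variance_fraction) <= 1e-12))
  expect_equal(sum(mdl$eigenvalues / sum(mdl$eigenvalues)), 1, tolerance = 1e-12)
  # sign canonicalization: largest-magnitude loading positive
  for (k in 1:10) expect_gt(mdl$components[k, which.max(abs(mdl$components[k, ]))], 0)
})

test_that("projection and reconstruction are exact inverses on the span", {
  withr::with_seed(34, Z <- matrix(rnorm(15 * 120), 15, 120))
  mdl <- fit_rnfl_pca(Z, K = 6L)
  # the mean map projects to zero weights
  expect_lt(max(abs(project_weights(mdl$mean, mdl))), 1e-10)
  # mean + 2 * component_3 projects to (0, 0, 2, 0, 0, 0)
  w <- project_weights(mdl$mean + 2 * mdl$components[3, ], mdl)
  expect_equal(unname(w), c(0, 0, 2, 0, 0, 0), tolerance = 1e-9)
  # project(reconstruct(w)) == w exactly
  W <- matrix(rnorm(5 * 6), 5, 6)
  expect_equal(unname(project_weights(reconstruct_map(W, mdl), mdl)), W,
               tolerance = 1e-9)
})

test_that("energy conservation and monotone reconstruction error", {
  withr::with_seed(35, Z <- matrix(rnorm(18 * 150), 18, 150))
  mdl10 <- fit_rnfl_pca(Z, K = 10L)
  W10 <- project_weights(Z, mdl10)
  Xc <- sweep(Z, 2, mdl10$mean)
  R10 <- Xc - W10 %*% mdl10$components
  # ||x - mean||^2 = sum_k w_k^2 + ||residual||^2 for every map
  expect_lt(max(abs(rowSums(Xc^2) - rowSums(W10^2) - rowSums(R10^2))), 1e-8)
  mdl5 <- fit_rnfl_pca(Z, K = 5L)
  W5 <- project_weights(Z, mdl5)
  R5 <- Xc - W5 %*% mdl5$components
  expect_true(all(rowSums(R10^2) <= rowSums(R5^2) + 1e-10))
})

test_that("change maps threshold loadings at the requested quantile", {
  withr::with_seed(36, Z <- matrix(rnorm(12 * 200), 12, 200))
  mdl <- fit_rnfl_pca(Z, K = 3L, map_dim = c(10, 20))
  expect_true(all(feature_change_map(mdl, 1, 0)))
  m <- feature_change_map(mdl, 2, 0.9)
  expect_equal(dim(m), c(10L, 20L))
  expect_equal(mean(m), 0.1, tolerance = 0.01)
  # single-pixel component
  mdl1 <- mdl
  mdl1$components[3, ] <- 0
  mdl1$components[3, 57] <- 1
  m1 <- feature_change_map(mdl1, 3, 0.99)
  expect_equal(which(as.vector(m1)), 57L)
})

test_that("K outside the admissible range is rejected", {
  withr::with_seed(37, Z <- matrix(rnorm(8 * 50), 8, 50))
  expect_error(fit_rnfl_pca(Z, K = 8L), "K")
  expect_error(fit_rnfl_pca(Z, K = 0L), "K")
})
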