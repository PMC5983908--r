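make_map <- function(values = matrix(50, 60, 80), laterality = "OD",
                     fovea = c(49.6, 29.5), onh = c(23.7, 27.7),
                     mm_per_px = 0.15) {
  if (laterality == "OS") {
    w <- ncol(values)
    fovea[1] <- (w - 1) - fovea[1]
    onh[1] <- (w - 1) - onh[1]
  }
  rnfl_map(values, laterality, fovea, onh, mm_per_px)
}

test_that("rnfl_map validates values, landmarks, and orientation", {
  expect_error(make_map(matrix(-1, 60, 80)), "negative")
  expect_error(rnfl_map(matrix(50, 60, 80), "OD", c(-1, 30), c(20, 30), 0.15),
               "outside")
  # OD requires ONH nasal (left) of fovea
  expect_error(rnfl_map(matrix(50, 60, 80), "OD", c(20, 30), c(50, 30), 0.15),
               "ordering|onh")
  expect_s3_class(make_map(), "rnfl_map")
})

test_that("mirroring is an involution that remaps landmarks", {
  m <- make_map(matrix(runif(60 * 80, 20, 120), 60, 80), laterality = "OS")
  m2 <- mirror_map(mirror_map(m))
  expect_identical(m2$values, m$values)
  expect_equal(m2$fovea, m$fovea)
  expect_equal(m2$laterality, m$laterality)
  w <- ncol(m$values)
  expect_equal(mirror_map(m)$fovea[1], (w - 1) - m$fovea[1])
})

test_that("flip_to_od leaves OD maps untouched and mirrors OS maps", {
  od <- make_map()
  expect_identical(flip_to_od(od), od)
  os <- make_map(matrix(runif(60 * 80, 20, 120), 60, 80), laterality = "OS")
  f <- flip_to_od(os)
  expect_equal(f$orientation, "OD")
  expect_equal(f$laterality, "OS")       # true eye is preserved
  expect_equal(f$fovea[1], (ncol(os$values) - 1) - os$fovea[1])
  expect_identical(f$values, os$values[, ncol(os$values):1])
  # flipping an already OD-oriented map is a no-op
  expect_identical(flip_to_od(f), f)
})

test_that("mean cpRNFL thickness extraction matches analytic fields", {
  # constant field
  m <- make_map(matrix(100, 60, 80))
  expect_equal(extract_mean_cprnflt(m), 100, tolerance = 1e-9)
  # radially symmetric field about the ONH: f(r) = 40 + 2 * r_px
  h <- 60; w <- 80
  onh <- c(30.0, 30.0)
  xg <- outer(rep(1, h), 0:(w - 1)); yg <- outer(0:(h - 1), rep(1, w))
  r <- sqrt((xg - onh[1])^2 + (yg - onh[2])^2)
  m2 <- rnfl_map(40 + 2 * r, "OD", c(60, 30), onh, 0.15)
  r_px <- 1.725 / 0.15
  expect_equal(extract_mean_cprnflt(m2), 40 + 2 * r_px, tolerance = 0.02)
  # oversampled quadrature oracle on a smooth asymmetric field
  m3 <- rnfl_map(test_image(), "OD", c(60, 30), onh, 0.15)
  oracle <- {
    ang <- seq(0, 2 * pi, length.out = 5121)[-5121]
    mean(rnflpca:::bilinear_sample(m3$values, onh[1] + r_px * cos(ang),
                                   onh[2] + r_px * sin(ang)))
  }
  expect_equal(extract_mean_cprnflt(m3), oracle, tolerance = 0.1)
})

test_that("cpRNFL circle leaving the grid is an error", {
  m <- rnfl_map(matrix(100, 60, 80), "OD", c(40, 30), c(5, 30), 0.15)
  expect_error(extract_mean_cprnflt(m), "exits")
})

test_that("resampling: identity, constant invariance, smooth round trip", {
  img <- test_image()
  expect_equal(resample_values(img, similarity_transform()), img,
               tolerance = 1e-12)
  cst <- matrix(77, 60, 80)
  out <- resample_values(cst, similarity_transform(tx = 3, ty = -2))
  expect_equal(unique(na.omit(as.vector(out))), 77)
  # fractional translation round trip on a smooth map
  tf <- similarity_transform(tx = 3.5, ty = 0)
  back <- resample_values(resample_values(img, tf), invert_transform(tf))
  interior <- back[10:50, 10:70] - img[10:50, 10:70]
  expect_lt(max(abs(interior)), 1)
})

test_that("resample_map transforms landmarks consistently", {
  m <- make_map(test_image())
  tf <- similarity_transform(s = 1.05, theta = 0.05, tx = 2, ty = 1)
  r <- resample_map(m, tf)
  expect_equal(r$fovea, apply_transform(tf, m$fovea))
  expect_equal(r$onh, apply_transform(tf, m$onh))
})
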