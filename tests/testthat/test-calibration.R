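test_that("fit_linear matches closed forms and the normal-equations oracle", {
  f <- fit_linear(c(1, 2, 3), c(2, 4, 6))
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r, 1, tolerance = 1e-12)
  # constant y: slope 0, r reported as 0 with a degeneracy flag
  fc <- fit_linear(1:5, rep(3, 5))
  expect_equal(fc$slope, 0, tolerance = 1e-12)
  expect_equal(fc$r, 0)
  expect_true(fc$degenerate)
  expect_error(fit_linear(rep(2, 4), 1:4), "degenerate")
  # brute-force normal equations oracle on random point sets
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(15); y <- 2.5 * x + rnorm(15)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    f <- fit_linear(x, y)
    expect_lt(abs(f$intercept - beta[1]), 1e-10)
    expect_lt(abs(f$slope - beta[2]), 1e-10)
  }
})

test_that("smax_to_diameter inverts the calibration exactly", {
  model <- structure(list(slope = 0.3447, intercept = 0, r = 0.99,
                          n_points = 10, slope_inverse = 1 / 0.3447),
                     class = "calibration_model")
  # s_max = 6.894 at 21.9 um voxels -> 20 px * 0.0219 mm = 0.438 mm
  expect_equal(smax_to_diameter(6.894, model, 0.0219), 0.438,
               tolerance = 1e-12)
  # unit case: one slope above the intercept is one voxel
  m2 <- structure(list(slope = 0.4, intercept = 1.3), class = "calibration_model")
  expect_equal(smax_to_diameter(1.3 + 0.4, m2, 0.05), 0.05,
               tolerance = 1e-12)
  # algebraic round trip at machine precision
  D <- c(3.5, 10, 47.25)
  s <- m2$intercept + m2$slope * D
  expect_equal(smax_to_diameter(s, m2, 0.0219), D * 0.0219,
               tolerance = 1e-14)
  # non-physical values are flagged as NA
  expect_true(is.na(smax_to_diameter(1.2, m2, 1)))
})

test_that("comparison regression is invariant to pair duplication", {
  set.seed(4)
  d_ct <- runif(20, 0.1, 1.2)
  d_ang <- 0.95 * d_ct + 0.1 + rnorm(20, sd = 0.03)
  c1 <- compare_dct_dang(data.frame(d_ct, d_ang))
  c2 <- compare_dct_dang(data.frame(d_ct = rep(d_ct, 2),
                                    d_ang = rep(d_ang, 2)))
  expect_equal(c1$slope, c2$slope, tolerance = 1e-12)
  expect_equal(c1$intercept, c2$intercept, tolerance = 1e-12)
  expect_equal(c1$r, c2$r, tolerance = 1e-12)
  # perfectly agreeing pairs
  c3 <- compare_dct_dang(data.frame(d_ct = c(0.2, 0.5, 0.9),
                                    d_ang = c(0.2, 0.5, 0.9)))
  expect_equal(c3$slope, 1, tolerance = 1e-12)
  expect_equal(c3$intercept, 0, tolerance = 1e-12)
  expect_equal(c3$r, 1, tolerance = 1e-12)
})

test_that("calibration points are collected per tube from projections", {
  # compact synthetic projections: two strips of known width, with a
  # sparse centerline carrying s_max values on the second image
  img <- matrix(0, 80, 120)
  img[, 28:39] <- 1   # 12 px strip at rows 28..39
  img[, 80:95] <- 1   # 16 px strip
  smax <- matrix(NA_real_, 80, 120)
  smax[, 34] <- 4; smax[, 88] <- 6
  iproj <- structure(list(pixels = img, view_angle = 0, pixel_size = 1,
                          kind = "intensity"), class = "projection2d")
  sproj <- structure(list(pixels = smax, view_angle = 0, pixel_size = 1,
                          kind = "attribute"), class = "projection2d")
  mk_lines <- function(yc) lapply(seq(20, 60, length.out = 5), function(x)
    line_selection(c(x, yc - 18), c(x, yc + 18)))
  pts <- collect_calibration_points(iproj, sproj,
                                    list(mk_lines(33.5), mk_lines(87.5)))
  expect_equal(nrow(pts), 2)
  expect_equal(pts$n_replicates, c(5, 5))
  expect_lt(abs(pts$d_proj[1] - 12), 0.5)
  expect_lt(abs(pts$d_proj[2] - 16), 0.5)
  expect_equal(pts$s_max, c(4, 6))
  # replicate homogeneity along a uniform strip
  expect_lt(pts$d_proj_sd[1] / pts$d_proj[1], 0.05)
})

test_that("calibration fit reports both orientations", {
  pts <- data.frame(d_proj = c(4, 10, 20, 40), s_max = c(1.5, 3.5, 7, 14))
  m <- fit_calibration(pts)
  expect_equal(m$slope, fit_linear(pts$d_proj, pts$s_max)$slope)
  expect_equal(m$slope_inverse, 1 / m$slope)
  m0 <- fit_calibration(pts, force_origin = TRUE)
  expect_equal(m0$intercept, 0)
})
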