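test_that("background correction cancels static structure", {
  img <- rect_band_image(24, 24, width = 6)
  frames <- array(rep(img, 12), c(24, 24, 12))
  bc <- background_correct(frames)
  expect_lt(max(abs(bc$frames)), 1e-12)
  # mean of a corrected sequence is the zero image
  sq <- generate_angio_sequence(img, 20, 8, noise_sd = 0.02, rng_seed = 1)
  bc2 <- background_correct(sq)
  expect_lt(max(abs(rowMeans(bc2$frames, dims = 2))), 1e-12)
})

test_that("corrected synthetic bolus has positive enhancement in vessels only", {
  img <- rect_band_image(24, 24, width = 6)
  sq <- generate_angio_sequence(img, 20, bolus_peak_frame = 10, noise_sd = 0,
                                rng_seed = 1, bolus_onset_frame = 5)
  bc <- background_correct(sq)
  outside <- bc$frames[, 1:5, 12]    # background columns
  inside <- bc$frames[, 12, 12]      # vessel center column after onset
  expect_lt(max(abs(outside - outside[1])), 1e-12)
  expect_true(all(inside > 0))
})

test_that("temporal moving average matches its window definition", {
  img <- matrix(1, 8, 8)
  frames <- array(rep(img, 15), c(8, 8, 15))
  sm <- temporal_moving_average(frames, 5)
  expect_equal(sm$frames, frames)  # constant sequence unchanged
  # single impulse of amplitude 11 spreads to 1 at the center of an
  # 11-frame window
  imp <- array(0, c(4, 4, 15))
  imp[2, 2, 8] <- 11
  smi <- temporal_moving_average(imp, 5)
  expect_equal(smi$frames[2, 2, 8], 1)
  expect_equal(smi$frames[2, 2, 2], 0)
  # halfwidth 0 is the identity
  expect_identical(temporal_moving_average(imp, 0)$frames, imp)
  expect_error(temporal_moving_average(imp[, , 1:9], 5), "shorter")
})

test_that("peak frame selection returns the bolus peak", {
  img <- rect_band_image(24, 24, width = 6)
  sq <- generate_angio_sequence(img, 30, bolus_peak_frame = 13, noise_sd = 0,
                                rng_seed = 1)
  bc <- background_correct(sq)
  expect_equal(select_peak_frame(bc), 13)
  # ROI excluding the vessel makes the result independent of vessel signal
  roi <- matrix(TRUE, 24, 24); roi[, 7:18] <- FALSE
  idx_no_vessel <- select_peak_frame(bc, roi)
  sq2 <- generate_angio_sequence(img * 2, 30, bolus_peak_frame = 13,
                                 noise_sd = 0, rng_seed = 1)
  expect_equal(select_peak_frame(background_correct(sq2), roi),
               idx_no_vessel)
  # ties resolve to the earliest frame
  flat <- array(0, c(4, 4, 12)); flat[, , 5] <- 1; flat[, , 9] <- 1
  expect_equal(select_peak_frame(flat), 5)
})

test_that("FWHM of a rectangular profile equals its width", {
  img <- rect_band_image(48, 64, width = 12, center = 32)
  ln <- line_selection(c(24, 8), c(24, 56))
  m <- fwhm_diameter(img, ln)
  expect_lt(abs(m$d_fwhm - 12), 0.25)   # within the sampling step
  expect_equal(m$d_fwhm, mean(m$widths[!is.na(m$widths)]))  # averaging rule
})

test_that("FWHM of a Gaussian profile matches 2 sqrt(2 ln 2) sigma", {
  sigma <- 4
  img <- gaussian_band_image(32, 96, sigma = sigma, center = 48)
  ln <- line_selection(c(16, 8), c(16, 88))
  m <- fwhm_diameter(img, ln)
  analytic <- 2 * sqrt(2 * log(2)) * sigma
  oracle <- brute_fwhm(function(x) exp(-(x - 48)^2 / (2 * sigma^2)), 8, 88)
  expect_lt(abs(m$d_fwhm - analytic), 0.1)
  expect_lt(abs(m$d_fwhm - oracle), 0.1)
})

test_that("FWHM is invariant to intensity scaling and translation", {
  img <- gaussian_band_image(32, 96, sigma = 5, center = 40)
  ln <- line_selection(c(10, 6), c(10, 80))
  d1 <- fwhm_diameter(img, ln)$d_fwhm
  d2 <- fwhm_diameter(img * 13.7, ln)$d_fwhm
  expect_equal(d1, d2, tolerance = 1e-12)
  # shift image and line together by 9 px along the profile
  img_sh <- gaussian_band_image(32, 96, sigma = 5, center = 49)
  ln_sh <- line_selection(c(10, 15), c(10, 89))
  d3 <- fwhm_diameter(img_sh, ln_sh)$d_fwhm
  expect_lt(abs(d3 - d1), 0.05)
})

test_that("degenerate FWHM inputs raise errors", {
  # monotone ramp: peak sits at the profile edge
  ramp <- matrix(rep(seq(0, 1, length.out = 32), each = 16), 16, 32)
  expect_error(fwhm_diameter(ramp, line_selection(c(8, 4), c(8, 30))),
               "edge|valid")
  # flat image: no crossings at all
  flat <- matrix(1, 16, 32)
  expect_error(fwhm_diameter(flat, line_selection(c(8, 4), c(8, 30))))
})

test_that("pixel size converts the FWHM to mm", {
  img <- rect_band_image(32, 64, width = 10, center = 32)
  m <- fwhm_diameter(img, line_selection(c(16, 10), c(16, 54)),
                     pixel_size = 0.0219)
  expect_equal(m$d_mm, m$d_fwhm * 0.0219, tolerance = 1e-12)
})
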