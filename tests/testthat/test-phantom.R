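test_that("axis-aligned tube has the right cross-section area", {
  ph <- generate_tube_volume(list(tube_spec(10)), c(40, 32, 32),
                             supersampling = 1)
  # tube runs along x: every yz cross-section is a discretized disk
  for (i in c(1, 20, 40)) {
    area <- sum(ph$voxels[i, , ] == 1)
    expect_lt(abs(area - pi * 25), 10)  # discretized circle, r = 5
  }
  # supersampled total mass converges to the exact area
  ph3 <- generate_tube_volume(list(tube_spec(10)), c(40, 32, 32),
                              supersampling = 4)
  expect_lt(abs(sum(ph3$voxels[20, , ]) - pi * 25), 1)
})

test_that("empty spec list yields a uniform background volume", {
  ph <- generate_tube_volume(list(), c(8, 8, 8))
  expect_true(all(ph$voxels == 0))
})

test_that("overlapping tubes are rejected", {
  sp1 <- tube_spec(10)
  sp2 <- tube_spec(10, center_offset = c(0, 4, 0))
  expect_error(generate_tube_volume(list(sp1, sp2), c(48, 48, 48)),
               "overlap")
})

test_that("rotated tube keeps its FWHM caliber", {
  # tube rotated (30, 15, 0), diameter 20: profile scan perpendicular to
  # the rotated axis through the supersampled volume recovers 20 +/- 1
  rot <- c(30, 15, 0)
  ph <- generate_tube_volume(list(tube_spec(20, axis_rotation = rot)),
                             c(64, 48, 48), supersampling = 3)
  g <- ph$ground_truth$geometry[[1]]
  # perpendicular direction in the xy plane (brute-force oracle: sample the
  # voxel grid along a line through the center, perpendicular to the axis)
  perp <- c(-g$axis[2], g$axis[1], 0)
  perp <- perp / sqrt(sum(perp^2))
  ts <- seq(-15, 15, by = 0.05)
  pts <- t(vapply(ts, function(t) g$center + t * perp, numeric(3)))
  idx <- round(pts) + 1
  vals <- ph$voxels[idx]
  half <- min(vals) + (max(vals) - min(vals)) / 2
  above <- range(which(vals >= half))
  w <- (above[2] - above[1]) * 0.05
  expect_lt(abs(w - 20), 1)
})

test_that("voxelization error decreases with supersampling", {
  err <- vapply(c(1, 2, 4), function(ss) {
    ph <- generate_tube_volume(list(tube_spec(7)), c(32, 24, 24),
                               supersampling = ss)
    abs(sum(ph$voxels[16, , ]) - pi * 3.5^2)
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-9))
})

test_that("rotation preserves length-normalized tube volume", {
  d <- c(64, 64, 64)
  ph0 <- generate_tube_volume(list(tube_spec(12)), d, supersampling = 3)
  ph1 <- generate_tube_volume(list(tube_spec(12, axis_rotation = c(30, 15, 0))),
                              d, supersampling = 3)
  # axis length inside the box, by clipping the center line to the volume
  axis_len <- function(ph) {
    g <- ph$ground_truth$geometry[[1]]
    ts <- vapply(1:3, function(k) {
      if (abs(g$axis[k]) < 1e-12) return(c(-Inf, Inf))
      sort(c((0 - g$center[k]) / g$axis[k],
             (d[k] - 1 - g$center[k]) / g$axis[k]))
    }, numeric(2))
    max(0, min(ts[2, ]) - max(ts[1, ]))
  }
  v0 <- sum(ph0$voxels > 0.5) / axis_len(ph0)
  v1 <- sum(ph1$voxels > 0.5) / axis_len(ph1)
  expect_lt(abs(v1 - v0) / v0, 0.02)
})

test_that("default calibration phantom matches its contract", {
  ph <- default_calibration_phantom()
  diams <- vapply(ph$ground_truth$specs, `[[`, numeric(1), "diameter")
  expect_equal(min(diams), 3.14, tolerance = 1e-12)
  expect_equal(max(diams), 62.8, tolerance = 1e-12)
  expect_length(diams, 10)
  # spacing rule: no two tube surfaces closer than the largest diameter
  geo <- ph$ground_truth$geometry
  for (i in 1:9) for (j in (i + 1):10) {
    dd <- vesselcal:::line_line_distance(geo[[i]]$center, geo[[i]]$axis,
                                         geo[[j]]$center, geo[[j]]$axis)
    expect_gte(dd - geo[[i]]$radius - geo[[j]]$radius, max(diams))
  }
  expect_true(all(dim(ph$voxels) >= 2 * max(diams)))
})

test_that("default calibration phantom is deterministic", {
  a <- default_calibration_phantom(axis_length = 96)
  b <- default_calibration_phantom(axis_length = 96)
  expect_identical(a$voxels, b$voxels)
})

test_that("tree phantom ground truth follows the generation rule", {
  spec <- tree_phantom_spec(n_generations = 3, child_ratio = 0.7,
                            root_diameter = 20, rng_seed = 3)
  tv <- generate_tree_volume(spec, c(96, 128, 96))
  segs <- tv$ground_truth$segments
  expect_equal(nrow(segs), 7)  # 1 + 2 + 4
  expect_equal(unique(segs$diameter[segs$generation == 3]), 20 * 0.7^2,
               tolerance = 1e-12)
  # determinism
  tv2 <- generate_tree_volume(spec, c(96, 128, 96))
  expect_identical(tv$voxels, tv2$voxels)
  # terminal diameter below 2 px is rejected at spec time
  expect_error(tree_phantom_spec(n_generations = 4, root_diameter = 10,
                                 child_ratio = 0.5), "below 2 px")
})

test_that("single-generation tree equals a plain cylinder in its interior", {
  spec <- tree_phantom_spec(n_generations = 1, root_diameter = 10,
                            rng_seed = 1, length_factor = 3.5)
  tv <- generate_tree_volume(spec, c(48, 48, 48))
  seg <- tv$ground_truth$segments
  tube <- generate_tube_volume(
    list(tube_spec(10, axis_rotation = c(0, 0, 90))), c(48, 48, 48))
  # compare cross-sections in the middle of the segment, away from the caps
  ymid <- round((seg$y0 + seg$y1) / 2) + 1
  expect_identical(tv$voxels[, ymid, ], tube$voxels[, ymid, ])
})

test_that("synthetic angio sequence honors its construction", {
  base <- rect_band_image(32, 32, width = 8)
  sq <- generate_angio_sequence(base, n_frames = 24, bolus_peak_frame = 10,
                                noise_sd = 0, rng_seed = 5,
                                bolus_onset_frame = 5)
  # before onset: static background exactly
  expect_identical(sq$frames[, , 1], sq$frames[, , 4])
  expect_true(all(sq$frames[, , 2] == sq$frames[1, 1, 2]))
  # maximal darkening at the peak frame
  vessel_px <- which(base == 1, arr.ind = TRUE)[1, ]
  trace <- sq$frames[vessel_px[1], vessel_px[2], ]
  expect_equal(which.min(trace), 10)
  # determinism with noise
  s1 <- generate_angio_sequence(base, 24, 10, noise_sd = 0.05, rng_seed = 2)
  s2 <- generate_angio_sequence(base, 24, 10, noise_sd = 0.05, rng_seed = 2)
  expect_identical(s1$frames, s2$frames)
  expect_error(generate_angio_sequence(base, n_frames = 8,
                                       bolus_peak_frame = 4))
})
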