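test_that("angle-0 MIP equals the per-column maximum (oracle)", {
  set.seed(3)
  v <- array(rnorm(20 * 18 * 16), c(20, 18, 16))
  p <- max_intensity_project(v, 0)
  oracle <- apply(v, c(1, 2), max)
  expect_identical(p$pixels, oracle)
  expect_equal(max(p$pixels), max(v))  # projected max = volume max
})

test_that("MIP of a constant volume is constant", {
  v <- array(2.5, c(16, 16, 16))
  p <- max_intensity_project(v, 0)
  expect_true(all(p$pixels == 2.5))
})

test_that("a single bright voxel lands at its rotated position", {
  v <- array(0, c(33, 9, 33))
  v[25, 5, 17] <- 1   # offset +8 in x from center (17, 17)
  p <- max_intensity_project(v, 90)
  got <- which(p$pixels == max(p$pixels, na.rm = TRUE), arr.ind = TRUE)
  # rotating 90 deg about y maps the +x offset onto the viewing axis,
  # so the bright spot should project at the x center
  expect_lt(abs(got[1, 1] - 17), 1.5)
  expect_equal(unname(got[1, 2]), 5L)
})

test_that("MIP is monotone and commutes with pointwise max at angle 0", {
  set.seed(9)
  a <- array(runif(16^3), c(16, 16, 16))
  b <- array(runif(16^3), c(16, 16, 16))
  pa <- max_intensity_project(a, 0)$pixels
  pb <- max_intensity_project(b, 0)$pixels
  pmaxab <- max_intensity_project(pmax(a, b), 0)$pixels
  expect_identical(pmaxab, pmax(pa, pb))
  expect_true(all(max_intensity_project(pmin(a, b), 0)$pixels <= pa))
})

test_that("tree attribute projection places nodes and respects periodicity", {
  tr <- structure(list(
    nodes = data.frame(id = 1L, x = 10, y = 12, z = 5, s_max = 9,
                       d_ct = NA_real_),
    edges = data.frame(from = integer(0), to = integer(0)),
    branches = list(1L), branch_generation = 1L, root = 1L),
    class = "centerline_tree")
  p0 <- project_tree_attribute(tr, "s_max", 0, c(32, 32))
  expect_equal(sum(!is.na(p0$pixels)), 1)
  expect_equal(p0$pixels[11, 13], 9)
  p360 <- project_tree_attribute(tr, "s_max", 360, c(32, 32))
  expect_identical(p0$pixels, p360$pixels)
  expect_error(project_tree_attribute(tr, "d_ct", 0, c(32, 32)), "not set")
})

test_that("projected tube s_max matches the 3D centerline readout", {
  ph <- small_tube(14, dims = c(48, 40, 40))
  r <- multiscale_vesselness(ph, vesselness_params(scales = 1:10))
  m <- flood_fill_segment(r, c(25, 21, 21), 0.05)
  tr <- skeletonize(m, prob = r)
  tr <- map_attribute_to_tree(tr, r, "s_max")
  pr <- project_tree_attribute(tr, "s_max", 0, c(48, 40))
  mid <- abs(tr$nodes$x - 23.5) < 8
  med3d <- median(tr$nodes$s_max[mid])
  ln <- line_selection(c(24, 6), c(24, 36))
  smax_line <- vesselcal:::sample_line_max(pr$pixels, ln)
  expect_lte(abs(smax_line - med3d), 1)
})
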