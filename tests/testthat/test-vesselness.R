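test_that("Hessian of a constant volume is zero", {
  v <- array(3.7, c(16, 16, 16))
  h <- hessian_at_scale(v, S = 2)
  for (comp in h) expect_lt(max(abs(comp)), 1e-12)
})

test_that("Hessian recovers the second derivative of a quadratic ramp", {
  # f = a x^2 is preserved by Gaussian smoothing up to a constant, so the
  # xx second difference is 2a, scale-normalized by S^gamma
  a <- 0.03
  d <- c(32, 16, 16)
  x <- array(rep((0:(d[1] - 1)), d[2] * d[3]), dim = d)
  v <- a * x^2
  S <- 2; gam <- 2
  h <- hessian_at_scale(v, S, gamma = gam)
  interior <- h$xx[12:20, 8, 8]
  expect_equal(interior, rep(2 * a * S^gam, length(interior)),
               tolerance = 1e-6)
  expect_lt(max(abs(h$xy[12:20, 8, 8])), 1e-10)
  expect_lt(max(abs(h$yz[12:20, 8, 8])), 1e-10)
})

test_that("Hessian components track an x<->y swap of the volume", {
  set.seed(42)
  v <- array(rnorm(16^3), c(16, 16, 16))
  vs <- aperm(v, c(2, 1, 3))
  h <- hessian_at_scale(v, 1.5)
  hs <- hessian_at_scale(vs, 1.5)
  expect_equal(aperm(h$xx, c(2, 1, 3)), hs$yy, tolerance = 1e-12)
  expect_equal(aperm(h$xy, c(2, 1, 3)), hs$xy, tolerance = 1e-12)
  expect_equal(aperm(h$xz, c(2, 1, 3)), hs$yz, tolerance = 1e-12)
})

test_that("scales beyond the volume size are rejected", {
  v <- array(0, c(16, 16, 16))
  expect_error(hessian_at_scale(v, 10), "half the smallest")
  expect_error(multiscale_vesselness(v, vesselness_params(scales = c(1, 10))),
               "half the smallest")
})

test_that("eigenvalues sort by absolute value", {
  mk <- function(a11, a22, a33, a12 = 0, a13 = 0, a23 = 0)
    lapply(list(xx = a11, xy = a12, xz = a13, yy = a22, yz = a23, zz = a33),
           array, dim = c(1, 1, 1))
  e <- sorted_eigenvalues(mk(-1, -4, 0.5))
  expect_equal(c(e$lam1, e$lam2, e$lam3), c(0.5, -1, -4))
  e0 <- sorted_eigenvalues(mk(0, 0, 0))
  expect_equal(c(e0$lam1, e0$lam2, e0$lam3), c(0, 0, 0))
})

test_that("eigenvalues are rotation invariant (numeric oracle)", {
  set.seed(7)
  for (rep in 1:20) {
    lam <- sort(rnorm(3))
    ang <- stats::runif(3, 0, 360)
    R <- rotation_matrix(ang)
    M <- R %*% diag(lam) %*% t(R)
    h <- lapply(list(xx = M[1, 1], xy = M[1, 2], xz = M[1, 3],
                     yy = M[2, 2], yz = M[2, 3], zz = M[3, 3]),
                array, dim = c(1, 1, 1))
    got <- sort(unname(unlist(sorted_eigenvalues(h))))
    oracle <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(got, oracle, tolerance = 1e-10)
  }
})

test_that("vesselness closed forms hold", {
  mkeig <- function(l1, l2, l3)
    list(lam1 = array(l1, c(1, 1, 1)), lam2 = array(l2, c(1, 1, 1)),
         lam3 = array(l3, c(1, 1, 1)))
  p <- vesselness_params(scales = 1, alpha = 0.5, beta = 0.5, c = 1)
  # zero eigenvalues: no structure
  expect_equal(as.numeric(vesselness_at_scale(mkeig(0, 0, 0), p)), 0)
  # ideal bright tube, k >> c: V -> 1 - exp(-1/(2 alpha^2)) = 1 - e^-2
  v <- as.numeric(vesselness_at_scale(mkeig(0, -100, -100), p))
  expect_equal(v, 1 - exp(-2), tolerance = 1e-10)
  # ideal bright plate: suppressed entirely
  expect_equal(as.numeric(vesselness_at_scale(mkeig(0, 0, -100), p)), 0)
  # positive lam2/lam3 fail the bright polarity
  expect_equal(as.numeric(vesselness_at_scale(mkeig(0, 100, 100), p)), 0)
  pd <- vesselness_params(scales = 1, c = 1, polarity = "dark-tubes")
  expect_equal(as.numeric(vesselness_at_scale(mkeig(0, 100, 100), pd)),
               1 - exp(-2), tolerance = 1e-10)
})

test_that("multiscale vesselness of a constant volume is empty", {
  v <- array(5, c(24, 24, 24))
  r <- multiscale_vesselness(v, vesselness_params(scales = 1:4))
  expect_true(all(r$probability == 0))
  expect_true(all(is.na(r$s_max)))
})

test_that("probability stays in [0, 1] and s_max in the scale list", {
  set.seed(11)
  v <- array(rnorm(24^3), c(24, 24, 24))
  p <- vesselness_params(scales = c(1, 2, 4))
  r <- multiscale_vesselness(v, p)
  expect_true(all(r$probability >= 0 & r$probability <= 1))
  expect_true(all(is.na(r$s_max) | r$s_max %in% p$scales))
  expect_true(all(is.na(r$s_max[r$probability == 0])))
})

test_that("centerline argmax scale tracks the tube diameter", {
  p <- vesselness_params(scales = 1:12)
  ph10 <- small_tube(10, dims = c(40, 40, 40))
  ph20 <- small_tube(20, dims = c(48, 48, 48))
  r10 <- multiscale_vesselness(ph10, p)
  r20 <- multiscale_vesselness(ph20, p)
  s10 <- r10$s_max[21, 21, 21]
  s20 <- r20$s_max[25, 25, 25]
  # slope ~0.345 scale/px: D = 20 should sit near scale 7, D = 10 near 3.5
  expect_lt(abs(s20 - 0.3447 * 20), 1.5)
  expect_gt(s20, s10)  # monotone in diameter
})

test_that("argmax scale is contrast invariant with auto c", {
  ph <- small_tube(8, dims = c(32, 32, 32))
  p <- vesselness_params(scales = 1:6)
  r1 <- multiscale_vesselness(ph, p)
  r2 <- multiscale_vesselness(intensity_volume(ph$voxels * 37), p)
  expect_identical(r1$s_max, r2$s_max)
})
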