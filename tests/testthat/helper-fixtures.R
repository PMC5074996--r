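# Small fixtures shared across tests; everything is generated in code.

# 2D image of a bright band of given width (rect cross-profile), vertical,
# centered at column `center`.
rect_band_image <- function(nx = 64, ny = 64, width = 12, center = ny / 2,
                            lo = 0, hi = 1) {
  img <- matrix(lo, nx, ny)
  half <- width / 2
  for (j in seq_len(ny)) {
    # supersampled pixel coverage of the band [center - half, center + half]
    a <- max(j - 0.5, center - half)
    b <- min(j + 0.5, center + half)
    cov <- max(0, b - a)
    img[, j] <- lo + (hi - lo) * cov
  }
  img
}

# 2D image whose rows all carry a Gaussian profile with the given sigma.
gaussian_band_image <- function(nx = 64, ny = 96, sigma = 4,
                                center = ny / 2, amp = 1) {
  prof <- amp * exp(-((seq_len(ny) - center)^2) / (2 * sigma^2))
  matrix(prof, nx, ny, byrow = TRUE)
}

# brute-force FWHM of an analytic profile function, by dense scan
brute_fwhm <- function(f, lo, hi, n = 200000) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  half <- min(y) + (max(y) - min(y)) / 2
  above <- which(y >= half)
  x[max(above)] - x[min(above)]
}

# a small axis-aligned tube volume (axis along x)
small_tube <- function(diameter = 10, dims = c(48, 48, 48),
                       supersampling = 3) {
  generate_tube_volume(list(tube_spec(diameter)), dims,
                       supersampling = supersampling)
}

# two-generation Y-shaped binary tree mask built directly from capsules
y_tree_phantom <- function(dims = c(64, 72, 48)) {
  generate_tree_volume(
    tree_phantom_spec(n_generations = 2, root_diameter = 9,
                      child_ratio = 0.75, branch_angle = 40, rng_seed = 7,
                      length_factor = 2.5),
    dims)
}

# FWHM of a profile across an analytic (continuous) cylinder: brute force
# on the exact chord-length indicator, independent of the rasterizer.
analytic_cylinder_fwhm <- function(diameter) diameter
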