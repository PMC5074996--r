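#' Ordinary least-squares line fit with Pearson correlation
#'
#' @param x,y numeric vectors (>= 3 points; x must vary).
#' @return list with `slope`, `intercept`, `r` and `n`. A constant `y` is
#'   reported as slope 0, r 0 with `degenerate = TRUE`.
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("degenerate fit: x values are all equal")
  fit <- stats::lm(y ~ x)
  degen <- stats::sd(y) == 0
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = if (degen) 0 else stats::cor(x, y),
       n = length(x), degenerate = degen)
}

#' Place replicate calibration line selections along each phantom tube
#'
#' Uses the phantom ground truth to draw, for every tube, `n_replicates`
#' line selections perpendicular to the projected tube axis, evenly spread
#' over the central portion of the visible strip. Lines are 2 D + 8 px long
#' so the tails sample background without touching neighboring tubes.
#'
#' @param phantom a `phantom_volume` of long tubes.
#' @param n_replicates measurements per tube (25 by default).
#' @param central_fraction fraction of the strip length to spread the
#'   replicate positions over.
#' @param angle projection view angle (must match the projections the lines
#'   are used on); only 0 is supported for line placement.
#' @return list (per tube) of lists of [line_selection()]s.
#' @export
calibration_lines <- function(phantom, n_replicates = 25,
                              central_fraction = 0.55, angle = 0) {
  stopifnot(inherits(phantom, "phantom_volume"),
            identical(phantom$ground_truth$kind, "tubes"))
  if (angle %% 360 != 0)
    stop("line placement is defined for the frontal (0 degree) view")
  d <- dim(phantom$voxels)
  lapply(seq_along(phantom$ground_truth$geometry), function(i) {
    g <- phantom$ground_truth$geometry[[i]]
    D <- 2 * g$radius
    # projected (x, y) geometry, 1-based pixel coordinates
    ctr <- g$center[1:2] + 1
    axdir <- g$axis[1:2]
    axdir <- axdir / sqrt(sum(axdir^2))
    perp <- c(-axdir[2], axdir[1])
    half_span <- central_fraction * d[1] / 2
    pos <- seq(-half_span, half_span, length.out = n_replicates)
    hl <- D + 4  # half-length of each line
    lapply(seq_along(pos), function(k) {
      q <- ctr + pos[k] * axdir
      line_selection(q - hl * perp, q + hl * perp,
                     label = sprintf("tube%02d_rep%02d", i, k))
    })
  })
}

sample_line_max <- function(img, line, t_range = c(0, 1)) {
  dvec <- line$p1 - line$p0
  len <- sqrt(sum(dvec^2)) * diff(t_range)
  nsamp <- as.integer(ceiling(len / 0.25)) + 1L
  tt <- seq(t_range[1], t_range[2], length.out = nsamp)
  xs <- line$p0[1] + tt * dvec[1]
  ys <- line$p0[2] + tt * dvec[2]
  # nearest pixel plus its 4-neighbourhood, so a 1-px-wide projected
  # centerline cannot slip between samples
  best <- -Inf
  for (off in list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    ix <- pmin(pmax(round(xs) + off[1], 1), nrow(img))
    iy <- pmin(pmax(round(ys) + off[2], 1), ncol(img))
    v <- img[cbind(ix, iy)]
    m <- suppressWarnings(max(v, na.rm = TRUE))
    if (m > best) best <- m
  }
  if (!is.finite(best)) NA_real_ else best
}

#' Collect S_MAX vs D_PROJ calibration points
#'
#' For each tube: D_PROJ is the mean FWHM diameter over the replicate line
#' positions on the intensity projection, and S_MAX is the mean (over the
#' same positions) of the maximum value along each line on the projected
#' S_MAX image.
#'
#' @param intensity_proj a `projection2d` of the phantom volume.
#' @param smax_proj the co-registered `projection2d` of the centerline-tree
#'   S_MAX attribute.
#' @param lines per-tube lists of replicate [line_selection()]s, e.g. from
#'   [calibration_lines()].
#' @param pixel_size optional mm per px for reporting.
#' @return data frame with one row per tube: `d_proj` (px), `s_max`,
#'   `n_replicates`, `d_proj_sd`.
#' @export
collect_calibration_points <- function(intensity_proj, smax_proj, lines,
                                       pixel_size = NULL) {
  stopifnot(inherits(intensity_proj, "projection2d"),
            inherits(smax_proj, "projection2d"))
  rows <- lapply(seq_along(lines), function(i) {
    dp <- numeric(0); sm <- numeric(0)
    for (ln in lines[[i]]) {
      meas <- fwhm_diameter(intensity_proj$pixels, ln,
                            pixel_size = pixel_size)
      # S_MAX is read across the tube itself: restrict the line to the
      # measured vessel span (FWHM width plus a 2 px margin on each side)
      # so centerline points of other structures along a long baseline
      # line are not picked up
      len <- sqrt(sum((ln$p1 - ln$p0)^2))
      half <- min(0.5, (meas$d_fwhm / 2 + 2) / len)
      mx <- sample_line_max(smax_proj$pixels, ln, c(0.5 - half, 0.5 + half))
      if (is.na(mx))
        stop(sprintf("line '%s' misses the tube on the S_MAX projection",
                     ln$label))
      dp <- c(dp, meas$d_fwhm); sm <- c(sm, mx)
    }
    data.frame(tube = i, d_proj = mean(dp), s_max = mean(sm),
               n_replicates = length(dp), d_proj_sd = stats::sd(dp))
  })
  do.call(rbind, rows)
}

#' Fit the S_MAX to D_PROJ linear calibration
#'
#' @param points data frame from [collect_calibration_points()] (columns
#'   `d_proj`, `s_max`).
#' @param force_origin fit without intercept.
#' @return A `calibration_model`: list with `slope` (scale units per px),
#'   `intercept`, `r`, `n_points`, and the points used. The reverse
#'   orientation (D on S) is reported alongside for transparency as
#'   `slope_inverse`.
#' @export
fit_calibration <- function(points, force_origin = FALSE) {
  stopifnot(all(c("d_proj", "s_max") %in% names(points)))
  if (nrow(points) < 3) stop("need at least 3 calibration points")
  if (force_origin) {
    fit <- stats::lm(s_max ~ d_proj + 0, data = points)
    slope <- unname(stats::coef(fit)[1]); intercept <- 0
    r <- stats::cor(points$d_proj, points$s_max)
  } else {
    f <- fit_linear(points$d_proj, points$s_max)
    slope <- f$slope; intercept <- f$intercept; r <- f$r
  }
  structure(list(slope = slope, intercept = intercept, r = r,
                 n_points = nrow(points),
                 slope_inverse = 1 / slope, points = points),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> S_MAX = %.4f * D_PROJ + %.4f (R = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r, x$n_points))
  invisible(x)
}

#' Convert S_MAX to a contrast-free caliber estimate D_CT
#'
#' Inverts the fitted calibration line: `d_ct = ((s_max - intercept) /
#' slope) * voxel_size`. Values at or below the intercept are non-physical
#' and returned as `NA`.
#'
#' @param s_max numeric vector of argmax Gaussian scales.
#' @param model a `calibration_model`.
#' @param voxel_size mm per voxel of the CT volume.
#' @return numeric vector of calibers in mm (`NA` where flagged).
#' @export
smax_to_diameter <- function(s_max, model, voxel_size) {
  stopifnot(inherits(model, "calibration_model"), voxel_size > 0)
  d <- (s_max - model$intercept) / model$slope * voxel_size
  d[!is.na(s_max) & s_max <= model$intercept] <- NA_real_
  d
}

#' Compare contrast-free (D_CT) and angiographic (D_ANG) calibers
#'
#' OLS regression of D_ANG on D_CT plus the Pearson correlation, the
#' orientation used for the in vivo cross-validation scatter.
#'
#' @param pairs data frame or 2-column matrix of (d_ct, d_ang) in mm
#'   (>= 3 rows).
#' @return A `comparison_result`: list with `slope`, `intercept` (mm),
#'   `r`, `n` and the pairs.
#' @export
compare_dct_dang <- function(pairs) {
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("d_ct", "d_ang")
  pairs <- pairs[stats::complete.cases(pairs[, 1:2]), , drop = FALSE]
  if (nrow(pairs) < 3) stop("need at least 3 (d_ct, d_ang) pairs")
  f <- fit_linear(pairs$d_ct, pairs$d_ang)
  structure(list(slope = f$slope, intercept = f$intercept, r = f$r,
                 n = nrow(pairs), pairs = pairs),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> D_ANG = %.3f * D_CT + %.3f mm (R = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' Run the full scale calibration on a tube phantom
#'
#' Convenience wrapper for the calibration workflow: multi-scale
#' vesselness, flood-fill segmentation seeded at the known tube centers,
#' skeletonization, S_MAX mapping, forward projection of the intensity
#' volume and of the tree S_MAX attribute at the frontal view, replicate
#' FWHM / line-maximum measurements, and the final linear fit.
#'
#' @param phantom a tube `phantom_volume` (default: the standard
#'   10-tube calibration phantom).
#' @param params a [vesselness_params()].
#' @param threshold flood-fill probability threshold.
#' @param n_replicates line positions per tube.
#' @param verbose print stage progress.
#' @return A `calibration_model` (with the collected points attached).
#' @export
calibrate_phantom <- function(phantom = default_calibration_phantom(),
                              params = vesselness_params(),
                              threshold = 0.05, n_replicates = 25,
                              verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  d <- dim(phantom$voxels)
  say("vesselness: %d x %d x %d, %d scales", d[1], d[2], d[3],
      length(params$scales))
  vr <- multiscale_vesselness(phantom, params)
  seeds <- do.call(rbind, lapply(phantom$ground_truth$geometry, function(g) {
    # seed on the tube axis at the volume mid-plane of the dominant axis dim
    dom <- which.max(abs(g$axis))
    t0 <- ((d[dom] - 1) / 2 - g$center[dom]) / g$axis[dom]
    round(g$center + t0 * g$axis) + 1
  }))
  say("flood fill from %d seeds at threshold %.3g", nrow(seeds), threshold)
  mask <- flood_fill_segment(vr, seeds, threshold)
  say("skeletonize (%d mask voxels)", sum(mask$voxels))
  tree <- skeletonize(mask, prob = vr)
  tree <- map_attribute_to_tree(tree, vr, "s_max")
  say("project and measure")
  iproj <- max_intensity_project(phantom, angle = 0)
  sproj <- project_tree_attribute(tree, "s_max", angle = 0, dims = d[1:2])
  lines <- calibration_lines(phantom, n_replicates = n_replicates)
  pts <- collect_calibration_points(iproj, sproj, lines)
  model <- fit_calibration(pts)
  model$tree <- tree
  model
}
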