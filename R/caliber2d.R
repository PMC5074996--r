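#' Line selection across a vessel
#'
#' Endpoints are in pixel coordinates (1-based, matching R matrix
#' indexing: the first coordinate indexes rows/x, the second columns/y).
#' The FWHM protocol measures `n_parallel` profiles: the central line plus
#' symmetric copies offset perpendicularly by `spacing` pixels.
#'
#' @param p0,p1 numeric length-2 endpoints; the line must be at least 3 px
#'   long.
#' @param n_parallel odd number of parallel profiles (default 5).
#' @param spacing perpendicular offset between profiles in px.
#' @param label optional name carried into reports.
#' @return A `line_selection` object.
#' @export
line_selection <- function(p0, p1, n_parallel = 5, spacing = 1,
                           label = NULL) {
  stopifnot(length(p0) == 2L, length(p1) == 2L)
  if (sqrt(sum((p1 - p0)^2)) < 3)
    stop("line selection must be at least 3 px long")
  if (n_parallel < 1 || n_parallel %% 2 == 0)
    stop("`n_parallel` must be odd and >= 1")
  structure(list(p0 = as.numeric(p0), p1 = as.numeric(p1),
                 n_parallel = as.integer(n_parallel), spacing = spacing,
                 label = label),
            class = "line_selection")
}

bilinear_sample <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  x <- pmin(pmax(x, 1), nx); y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1); y0 <- pmin(floor(y), ny - 1)
  fx <- x - x0; fy <- y - y0
  img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    img[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    img[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    img[cbind(x0 + 1, y0 + 1)] * fx * fy
}

# FWHM of one sampled profile; returns width in px or NA if invalid.
# step: spacing (px) between consecutive samples.
profile_fwhm <- function(vals, step) {
  n <- length(vals)
  ntail <- max(1L, floor(0.1 * n))
  base <- min(mean(vals[seq_len(ntail)]), mean(vals[seq(n - ntail + 1, n)]))
  pk <- which.max(vals)
  if (pk == 1L || pk == n) return(structure(NA_real_, edge = TRUE))
  half <- base + (vals[pk] - base) / 2
  # crossing nearest the peak on each side, sub-pixel by linear interpolation
  left <- NA_real_
  for (i in seq(pk - 1, 1)) {
    if (vals[i] <= half) {
      left <- i + (half - vals[i]) / (vals[i + 1] - vals[i])
      break
    }
  }
  right <- NA_real_
  for (i in seq(pk + 1, n)) {
    if (vals[i] <= half) {
      right <- i - (half - vals[i]) / (vals[i - 1] - vals[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) * step
}

#' FWHM vessel diameter from an image line selection
#'
#' For each of the `n_parallel` profiles the image is sampled by bilinear
#' interpolation at steps of at most 0.25 px; the baseline is the lower of
#' the two outer-10% tail means, the half level lies midway between
#' baseline and peak, and the width is the distance between the two
#' half-level crossings nearest the peak (each localized by linear
#' interpolation between samples). Profiles without two crossings are
#' dropped and reported; the diameter is the mean of the valid widths.
#' The measurement expects bright vessels (enhancement images or MIPs of
#' bright-vessel volumes).
#'
#' @param image 2D numeric matrix.
#' @param line a [line_selection()].
#' @param pixel_size optional mm per px; if given, `d_mm` is reported.
#' @return A `diameter_measurement`: list with `line`, per-profile
#'   `widths` (px, `NA` for dropped profiles), `d_fwhm` (px), `d_mm`,
#'   and `n_dropped`.
#' @export
fwhm_diameter <- function(image, line, pixel_size = NULL) {
  stopifnot(is.matrix(image), inherits(line, "line_selection"))
  dvec <- line$p1 - line$p0
  len <- sqrt(sum(dvec^2))
  u <- dvec / len
  perp <- c(-u[2], u[1])
  nsamp <- as.integer(ceiling(len / 0.25)) + 1L
  tt <- seq(0, 1, length.out = nsamp)
  step <- len / (nsamp - 1)
  offs <- (seq_len(line$n_parallel) - (line$n_parallel + 1) / 2) *
    line$spacing
  widths <- numeric(line$n_parallel)
  edge_peak <- FALSE
  for (k in seq_along(offs)) {
    q0 <- line$p0 + offs[k] * perp
    xs <- q0[1] + tt * dvec[1]
    ys <- q0[2] + tt * dvec[2]
    vals <- bilinear_sample(image, xs, ys)
    w <- profile_fwhm(vals, step)
    if (!is.na(w)) widths[k] <- w
    else {
      widths[k] <- NA_real_
      if (isTRUE(attr(w, "edge"))) edge_peak <- TRUE
    }
  }
  valid <- !is.na(widths)
  if (!any(valid)) {
    if (edge_peak) stop("peak at profile edge: line selection too short")
    stop("no valid FWHM profile on this line selection")
  }
  d <- mean(widths[valid])
  structure(list(line = line, widths = widths, d_fwhm = d,
                 d_mm = if (is.null(pixel_size)) NA_real_ else d * pixel_size,
                 n_dropped = sum(!valid)),
            class = "diameter_measurement")
}

#' @export
print.diameter_measurement <- function(x, ...) {
  cat(sprintf("<diameter_measurement> d_fwhm = %.3f px", x$d_fwhm))
  if (!is.na(x$d_mm)) cat(sprintf(" (%.4f mm)", x$d_mm))
  cat(sprintf(", %d/%d profiles valid\n",
              sum(!is.na(x$widths)), length(x$widths)))
  invisible(x)
}

#' Background-correct an angiography sequence
#'
#' Replaces each frame by (temporal mean - frame), so that iodinated
#' (darker) vessels become positive enhancement while static structures
#' cancel to ~0.
#'
#' @param frames an `angio_sequence` (see [generate_angio_sequence()]) or a
#'   3D array (nx, ny, n_frames) with at least 2 frames.
#' @return the sequence with corrected frames.
#' @export
background_correct <- function(frames) {
  sq <- as_angio(frames)
  if (dim(sq$frames)[3] < 2) stop("need at least 2 frames")
  mn <- rowMeans(sq$frames, dims = 2)
  sq$frames <- array(as.numeric(mn) - sq$frames, dim = dim(sq$frames))
  sq
}

as_angio <- function(x) {
  if (inherits(x, "angio_sequence")) return(x)
  if (is.array(x) && length(dim(x)) == 3L)
    return(structure(list(frames = x, frame_interval = NA_real_,
                          bolus_onset_frame = NA_integer_,
                          bolus_peak_frame = NA_integer_,
                          ground_truth_diameters = NULL),
                     class = "angio_sequence"))
  stop("expected an angio_sequence or 3D array")
}

#' Temporal moving average of an angiography sequence
#'
#' Frame t becomes the mean of frames `[t - halfwidth, t + halfwidth]`
#' ("five images either side" by default); the window is truncated at the
#' sequence edges.
#'
#' @param frames an `angio_sequence` or 3D array with at least
#'   `2 * halfwidth + 1` frames.
#' @param halfwidth window half-width in frames.
#' @return the smoothed sequence.
#' @export
temporal_moving_average <- function(frames, halfwidth = 5) {
  sq <- as_angio(frames)
  nt <- dim(sq$frames)[3]
  if (nt < 2 * halfwidth + 1)
    stop("sequence shorter than the moving-average window")
  if (halfwidth == 0) return(sq)
  cum <- apply(sq$frames, c(1, 2), cumsum)          # (t, x, y)
  out <- array(0, dim = dim(sq$frames))
  for (t in seq_len(nt)) {
    lo <- max(1L, t - halfwidth); hi <- min(nt, t + halfwidth)
    s <- cum[hi, , ] - (if (lo > 1) cum[lo - 1, , ] else 0)
    out[, , t] <- s / (hi - lo + 1)
  }
  sq$frames <- out
  sq
}

#' Select the peak-enhancement frame
#'
#' Returns the index of the frame with the largest total enhancement
#' (sum of values) within the region of interest, on a processed
#' (background-corrected) sequence. Ties take the earliest frame.
#'
#' @param frames an `angio_sequence` or 3D array of enhancement frames.
#' @param roi optional logical matrix selecting pixels to sum over.
#' @return integer frame index.
#' @export
select_peak_frame <- function(frames, roi = NULL) {
  sq <- as_angio(frames)
  nt <- dim(sq$frames)[3]
  tot <- vapply(seq_len(nt), function(t) {
    f <- sq$frames[, , t]
    if (!is.null(roi)) sum(f[roi]) else sum(f)
  }, numeric(1))
  which.max(tot)  # which.max returns the first (earliest) maximum
}
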