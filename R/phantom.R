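#' Tube specification for synthetic phantoms
#'
#' Describes one straight cylinder ("long tube") in a phantom volume. The
#' canonical tube axis runs along x; `axis_rotation` is an extrinsic
#' (x, then y, then z) rotation in degrees applied to that axis about the
#' volume center. Tubes are bright on a dark background, matching
#' water-density vessels against air-filled lung parenchyma.
#'
#' @param diameter tube diameter in voxels (px), > 0.
#' @param center_offset 3-vector, offset of the tube center from the volume
#'   center, in voxels.
#' @param axis_rotation (x, y, z) rotation in degrees, see
#'   [rotation_matrix()].
#' @param foreground_value,background_value dimensionless intensities;
#'   foreground must exceed background.
#' @return A `tube_spec` object.
#' @export
tube_spec <- function(diameter, center_offset = c(0, 0, 0),
                      axis_rotation = c(0, 0, 0),
                      foreground_value = 1, background_value = 0) {
  if (diameter <= 0) stop("`diameter` must be positive")
  if (foreground_value <= background_value)
    stop("`foreground_value` must exceed `background_value`")
  stopifnot(length(center_offset) == 3L, length(axis_rotation) == 3L)
  structure(list(diameter = diameter, center_offset = center_offset,
                 axis_rotation = axis_rotation,
                 foreground_value = foreground_value,
                 background_value = background_value),
            class = "tube_spec")
}

tube_geometry <- function(spec, dims) {
  ctr <- (dims - 1) / 2
  axis <- as.numeric(rotation_matrix(spec$axis_rotation) %*% c(1, 0, 0))
  list(center = ctr + spec$center_offset, axis = axis,
       radius = spec$diameter / 2)
}

# distance between two infinite lines (c1, u1), (c2, u2)
line_line_distance <- function(c1, u1, c2, u2) {
  cr <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  d <- c2 - c1
  ncr <- sqrt(sum(cr^2))
  if (ncr < 1e-9) {  # parallel
    proj <- d - sum(d * u1) * u1
    sqrt(sum(proj^2))
  } else {
    abs(sum(d * cr)) / ncr
  }
}

#' Generate a volume of long synthetic tubes
#'
#' Rasterizes straight cylinders that span the full volume, with
#' partial-volume (supersampled) antialiasing at the surfaces. Overlapping
#' tubes are rejected: scale calibration requires isolated tubes.
#'
#' @param specs list of [tube_spec()] objects (all sharing the same
#'   foreground/background values).
#' @param dims integer length-3 volume dimensions; each must be at least
#'   twice the largest tube diameter.
#' @param supersampling subvoxel sampling factor per axis for edge
#'   antialiasing (>= 1); 3 by default.
#' @param voxel_size voxel edge length in mm.
#' @return A `phantom_volume` (also an `intensity_volume`) whose
#'   `ground_truth` element records the tube specs and their world-space
#'   center/axis geometry.
#' @export
generate_tube_volume <- function(specs, dims, supersampling = 3,
                                 voxel_size = 1) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 3L), supersampling >= 1)
  if (length(specs) > 0) {
    if (!all(vapply(specs, inherits, logical(1), "tube_spec")))
      stop("`specs` must be a list of tube_spec objects")
    dmax <- max(vapply(specs, function(s) s$diameter, numeric(1)))
    if (any(dims < 2 * dmax))
      stop("grid dimensions must be at least twice the largest tube diameter")
    fg <- vapply(specs, function(s) s$foreground_value, numeric(1))
    bg <- vapply(specs, function(s) s$background_value, numeric(1))
    if (length(unique(fg)) > 1L || length(unique(bg)) > 1L)
      stop("all tubes in one volume must share foreground/background values")
    geo <- lapply(specs, tube_geometry, dims = dims)
    n <- length(geo)
    if (n > 1) {
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        d <- line_line_distance(geo[[i]]$center, geo[[i]]$axis,
                                geo[[j]]$center, geo[[j]]$axis)
        if (d < geo[[i]]$radius + geo[[j]]$radius)
          stop(sprintf("tubes %d and %d overlap", i, j))
      }
    }
    p0 <- do.call(rbind, lapply(geo, `[[`, "center"))
    ax <- do.call(rbind, lapply(geo, `[[`, "axis"))
    r <- vapply(geo, `[[`, numeric(1), "radius")
    vox <- cpp_rasterize_tubes(dims, p0, ax, r, rep(-Inf, n), rep(Inf, n),
                               fg[1], bg[1], as.integer(supersampling))
  } else {
    vox <- rep(0, prod(dims))
    geo <- list()
  }
  out <- intensity_volume(array(vox, dim = dims), voxel_size)
  out$ground_truth <- list(kind = "tubes", specs = specs, geometry = geo)
  out$rng_seed <- NULL
  class(out) <- c("phantom_volume", class(out))
  out
}

#' Default scale-calibration phantom
#'
#' A deterministic volume of 10 parallel non-overlapping long tubes with
#' diameters geometrically spaced from 3.14 to 62.8 px, all rotated by
#' (x = 30, y = 15, z = 0) degrees. Adjacent tube surfaces are separated by
#' at least the largest tube diameter so that neighboring tubes do not
#' interact through the vesselness filter or line selections. Tube centers
#' are spread along the image-vertical (y) direction, which is perpendicular
#' to the rotated tube axis, so a 0-degree projection shows ten disjoint
#' horizontal strips.
#'
#' @param n_tubes number of tubes.
#' @param diameter_range smallest and largest diameter in px.
#' @param rotation extrinsic rotation (degrees) applied to every tube axis.
#' @param axis_length extent (voxels) of the volume along the dominant axis
#'   direction of the tubes.
#' @param supersampling edge antialiasing factor, see
#'   [generate_tube_volume()].
#' @param margin clearance (voxels) added around the tube bundle.
#' @return A `phantom_volume`; see [generate_tube_volume()].
#' @export
default_calibration_phantom <- function(n_tubes = 10,
                                        diameter_range = c(3.14, 62.8),
                                        rotation = c(30, 15, 0),
                                        axis_length = 200,
                                        supersampling = 3,
                                        margin = 12) {
  diams <- exp(seq(log(diameter_range[1]), log(diameter_range[2]),
                   length.out = n_tubes))
  radii <- diams / 2
  dmax <- max(diams)
  gap <- dmax + 2  # surface-to-surface clearance
  axis <- as.numeric(rotation_matrix(rotation) %*% c(1, 0, 0))
  # spread direction: perpendicular to the axis, as close to y as possible
  v <- c(0, 1, 0) - sum(c(0, 1, 0) * axis) * axis
  if (sqrt(sum(v^2)) < 1e-6) v <- c(1, 0, 0) - sum(c(1, 0, 0) * axis) * axis
  v <- v / sqrt(sum(v^2))
  # center offsets along v
  off <- numeric(n_tubes)
  for (i in seq_len(n_tubes)[-1])
    off[i] <- off[i - 1] + radii[i - 1] + radii[i] + gap
  off <- off - (min(off - radii) + max(off + radii)) / 2  # center the bundle
  dom <- which.max(abs(axis))
  span <- max(off + radii) - min(off - radii)
  dims <- integer(3)
  for (d in 1:3) {
    if (d == dom) {
      dims[d] <- as.integer(ceiling(axis_length))
    } else {
      drift <- abs(axis[d]) / abs(axis[dom]) * axis_length
      dims[d] <- as.integer(ceiling(abs(v[d]) * span + 1.1 * dmax + drift +
                                      2 * margin))
    }
    dims[d] <- max(dims[d], as.integer(ceiling(2 * dmax)) + 2L)
  }
  specs <- lapply(seq_len(n_tubes), function(i)
    tube_spec(diams[i], center_offset = off[i] * v, axis_rotation = rotation))
  generate_tube_volume(specs, dims, supersampling = supersampling)
}

#' Branching-tree phantom specification
#'
#' @param n_generations number of branch generations (>= 1).
#' @param root_diameter root segment diameter in px.
#' @param child_ratio diameter scale factor per generation, in (0, 1).
#' @param branch_angle angle (degrees) between a child segment and its
#'   parent direction.
#' @param rng_seed integer seed controlling branch azimuths.
#' @param length_factor segment length as a multiple of its diameter.
#' @return A `tree_phantom_spec` object.
#' @export
tree_phantom_spec <- function(n_generations = 3, root_diameter = 40,
                              child_ratio = 0.7, branch_angle = 35,
                              rng_seed = 1, length_factor = 1.9) {
  stopifnot(n_generations >= 1, root_diameter > 0,
            child_ratio > 0, child_ratio < 1)
  term <- root_diameter * child_ratio^(n_generations - 1)
  if (term < 2)
    stop("terminal segment diameter would be below 2 px")
  structure(list(n_generations = n_generations,
                 root_diameter = root_diameter, child_ratio = child_ratio,
                 branch_angle = branch_angle, rng_seed = rng_seed,
                 length_factor = length_factor),
            class = "tree_phantom_spec")
}

#' Generate a branching vascular-tree phantom
#'
#' A connected binary tree of cylindrical segments (capsules, so joints are
#' smooth). The root grows along +y from near the bottom face; each segment
#' spawns two children tilted by `branch_angle` with azimuths drawn
#' reproducibly from `rng_seed`. Per-segment ground-truth diameters and
#' generations are recorded.
#'
#' @param spec a [tree_phantom_spec()].
#' @param dims integer length-3 volume dimensions.
#' @param supersampling edge antialiasing factor.
#' @param voxel_size voxel edge length in mm.
#' @return A `phantom_volume` whose `ground_truth$segments` is a data frame
#'   with segment endpoints, diameter and generation.
#' @export
generate_tree_volume <- function(spec, dims, supersampling = 3,
                                 voxel_size = 1) {
  stopifnot(inherits(spec, "tree_phantom_spec"))
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 3L))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$rng_seed)
  ctr <- (dims - 1) / 2
  segs <- list()
  grow <- function(p0, dir, diam, gen) {
    len <- spec$length_factor * diam
    p1 <- p0 + len * dir
    segs[[length(segs) + 1]] <<- c(p0, p1, diam, gen)
    if (gen < spec$n_generations) {
      az <- stats::runif(1, 0, 2 * pi)
      th <- spec$branch_angle * pi / 180
      # orthonormal frame around dir
      ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
      e1 <- ref - sum(ref * dir) * dir
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
              dir[3] * e1[1] - dir[1] * e1[3],
              dir[1] * e1[2] - dir[2] * e1[1])
      for (phi in c(az, az + pi)) {
        cd <- cos(th) * dir + sin(th) * (cos(phi) * e1 + sin(phi) * e2)
        cd <- cd / sqrt(sum(cd^2))
        grow(p1, cd, diam * spec$child_ratio, gen + 1)
      }
    }
  }
  root_len_total <- sum(spec$length_factor * spec$root_diameter *
                          spec$child_ratio^(seq_len(spec$n_generations) - 1))
  start_y <- max(4, (dims[2] - 1) / 2 - root_len_total * 0.55)
  grow(c(ctr[1], start_y, ctr[3]), c(0, 1, 0), spec$root_diameter, 1)
  m <- do.call(rbind, segs)
  seg_df <- data.frame(x0 = m[, 1], y0 = m[, 2], z0 = m[, 3],
                       x1 = m[, 4], y1 = m[, 5], z1 = m[, 6],
                       diameter = m[, 7], generation = as.integer(m[, 8]))
  # All segment ends except the root's entry point must fit inside the
  # volume: a tree clipped at its root by the field of view is how real
  # data looks, but clipped branch tips corrupt the ground truth.
  ends <- rbind(as.matrix(seg_df[, c("x0", "y0", "z0")])[-1, , drop = FALSE],
                as.matrix(seg_df[, c("x1", "y1", "z1")]))
  rr <- c(seg_df$diameter[-1], seg_df$diameter) / 2
  if (any(ends - rr < 0) ||
      any(ends + rr > matrix(dims - 1, nrow(ends), 3, byrow = TRUE)))
    warning("tree does not fit inside `dims`: clipped branch tips will ",
            "distort the ground truth at the volume faces")
  dvec <- cbind(seg_df$x1 - seg_df$x0, seg_df$y1 - seg_df$y0,
                seg_df$z1 - seg_df$z0)
  lens <- sqrt(rowSums(dvec^2))
  ax <- dvec / lens
  vox <- cpp_rasterize_tubes(dims, as.matrix(seg_df[, c("x0", "y0", "z0")]),
                             ax, seg_df$diameter / 2,
                             rep(0, nrow(seg_df)), lens,
                             1, 0, as.integer(supersampling))
  out <- intensity_volume(array(vox, dim = dims), voxel_size)
  out$ground_truth <- list(kind = "tree", spec = spec, segments = seg_df)
  out$rng_seed <- spec$rng_seed
  class(out) <- c("phantom_volume", class(out))
  out
}

#' Generate a synthetic bolus-enhanced angiography sequence
#'
#' Emulates contrast-agent passage for testing the 2D analysis chain:
#' each frame is a static background minus a time-varying darkening of the
#' vessel pattern (iodinated vessels absorb x rays), plus i.i.d. Gaussian
#' noise. Enhancement ramps linearly from `bolus_onset_frame` to
#' `bolus_peak_frame` and decays exponentially afterwards.
#'
#' @param base 2D matrix (e.g. the pixels of a projected phantom) used as
#'   the vessel pattern; values are rescaled to `[0, 1]`.
#' @param n_frames number of frames (>= 11 so an 11-frame moving average
#'   fits).
#' @param bolus_peak_frame 1-based index of maximal enhancement.
#' @param noise_sd standard deviation of the additive noise.
#' @param rng_seed integer seed for the noise.
#' @param bolus_onset_frame 1-based frame at which enhancement starts;
#'   defaults to half way to the peak.
#' @param amplitude peak darkening as a fraction of the background level.
#' @param frame_interval seconds between frames (30 Hz acquisition by
#'   default).
#' @param ground_truth_diameters optional named numeric vector of known
#'   vessel diameters (px), carried through for validation.
#' @return An `angio_sequence`: list with `frames` (nx x ny x n_frames
#'   array), `frame_interval`, `bolus_onset_frame`, `bolus_peak_frame` and
#'   `ground_truth_diameters`.
#' @export
generate_angio_sequence <- function(base, n_frames = 200, bolus_peak_frame,
                                    noise_sd = 0, rng_seed = 1,
                                    bolus_onset_frame = NULL,
                                    amplitude = 0.5,
                                    frame_interval = 1 / 30,
                                    ground_truth_diameters = NULL) {
  if (inherits(base, "projection2d")) base <- base$pixels
  stopifnot(is.matrix(base), n_frames >= 11,
            bolus_peak_frame >= 1, bolus_peak_frame <= n_frames)
  if (is.null(bolus_onset_frame))
    bolus_onset_frame <- max(1, floor(bolus_peak_frame / 2))
  rng <- range(base, finite = TRUE)
  v <- if (diff(rng) > 0) (base - rng[1]) / diff(rng) else base * 0
  v[!is.finite(v)] <- 0
  bg <- 0.75
  e <- numeric(n_frames)
  ramp <- seq(bolus_onset_frame, bolus_peak_frame)
  e[ramp] <- (ramp - bolus_onset_frame) /
    max(1, bolus_peak_frame - bolus_onset_frame)
  if (bolus_peak_frame < n_frames) {
    tail_idx <- seq(bolus_peak_frame + 1, n_frames)
    tau <- max(1, (n_frames - bolus_peak_frame) / 3)
    e[tail_idx] <- exp(-(tail_idx - bolus_peak_frame) / tau)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(rng_seed)
  frames <- array(0, dim = c(dim(v), n_frames))
  for (t in seq_len(n_frames)) {
    f <- bg - amplitude * e[t] * v
    if (noise_sd > 0) f <- f + rnorm(length(f), sd = noise_sd)
    frames[, , t] <- f
  }
  structure(list(frames = frames, frame_interval = frame_interval,
                 bolus_onset_frame = bolus_onset_frame,
                 bolus_peak_frame = bolus_peak_frame,
                 ground_truth_diameters = ground_truth_diameters),
            class = "angio_sequence")
}
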