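#' Construct an intensity volume
#'
#' A 3D scalar grid with an isotropic voxel size, the common container for
#' micro-CT reconstructions and synthetic phantoms. Voxel (i, j, k) (1-based
#' in R) has its center at world coordinate (i-1, j-1, k-1) voxels; exported
#' coordinates are converted to mm with origin at the volume corner.
#'
#' @param voxels 3D numeric array, all values finite, at least 3 per axis.
#' @param voxel_size isotropic voxel edge length in mm.
#' @return An object of class `intensity_volume`: a list with elements
#'   `voxels` and `voxel_size`.
#' @export
intensity_volume <- function(voxels, voxel_size = 1) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (any(dim(voxels) < 3L))
    stop("volume must have at least 3 voxels per axis")
  if (!all(is.finite(voxels)))
    stop("all voxel values must be finite")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number")
  structure(list(voxels = voxels, voxel_size = voxel_size),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<intensity_volume> %d x %d x %d voxels, %.4g mm/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.intensity_volume <- function(x) dim(x$voxels)

as_volume <- function(x, voxel_size = 1) {
  if (inherits(x, "intensity_volume")) return(x)
  intensity_volume(x, voxel_size)
}

#' Extrinsic rotation matrix
#'
#' Rotations are applied extrinsically about the fixed x, then y, then z
#' axes (R = Rz Ry Rx), about the volume center. This is the convention used
#' for all phantom tube orientations.
#'
#' @param angles numeric length-3, degrees about (x, y, z).
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(angles) {
  stopifnot(length(angles) == 3L)
  a <- angles * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}
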