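#' Maximum intensity forward projection
#'
#' Parallel-beam MIP: the volume is rotated by `angle` degrees about the
#' vertical (y) axis via trilinear interpolation and the maximum is taken
#' along the viewing (z) axis. At angle 0 the projection is the exact
#' per-column maximum. Pixels whose ray never intersects the volume are
#' `NA`.
#'
#' @param vol an [intensity_volume()] or 3D array; all values finite.
#' @param angle view angle in degrees (normalized to `[0, 360)`);
#'   frontal = 0, right/left anterior oblique = +/-45.
#' @param pixel_size mm per pixel; defaults to the voxel size.
#' @return A `projection2d`: list with `pixels` (nx x ny matrix),
#'   `view_angle`, `pixel_size`, `kind = "intensity"`.
#' @export
max_intensity_project <- function(vol, angle = 0, pixel_size = NULL) {
  vol <- as_volume(vol)
  if (is.null(pixel_size)) pixel_size <- vol$voxel_size
  a <- angle %% 360
  px <- cpp_mip(as.numeric(vol$voxels), dim(vol$voxels), a)
  structure(list(pixels = px, view_angle = a, pixel_size = pixel_size,
                 kind = "intensity"),
            class = "projection2d")
}

#' Forward-project a centerline-tree attribute
#'
#' Rotates node coordinates about the vertical (y) axis and projects them
#' orthographically along z onto a 2D grid; each pixel takes the maximum
#' attribute value over the nodes landing on it. Background pixels are
#' `NA`. Matches the view geometry of [max_intensity_project()] so the two
#' projections are co-registered.
#'
#' @param tree a `centerline_tree` with the attribute set on all nodes.
#' @param attribute node attribute name, e.g. `"s_max"` or `"d_ct"`.
#' @param angle view angle in degrees about the vertical axis.
#' @param dims integer length-2 image dimensions (nx, ny); usually the
#'   first two dimensions of the source volume.
#' @param dilate if `TRUE`, thicken each projected node to 3x3 pixels
#'   (for display).
#' @param pixel_size mm per pixel.
#' @param z_center rotation center along z; pass `(nz - 1) / 2` of the
#'   source volume to co-register oblique views with
#'   [max_intensity_project()] (at angle 0 the choice has no effect).
#'   Defaults to the midpoint of the node cloud.
#' @return A `projection2d` with `kind = "attribute"`.
#' @export
project_tree_attribute <- function(tree, attribute, angle, dims,
                                   dilate = FALSE, pixel_size = 1,
                                   z_center = NULL) {
  stopifnot(inherits(tree, "centerline_tree"), length(dims) == 2L)
  vals <- tree$nodes[[attribute]]
  if (is.null(vals) || any(is.na(vals)))
    stop(sprintf("attribute '%s' is not set on all nodes", attribute))
  a <- angle %% 360
  th <- a * pi / 180
  cx <- (dims[1] - 1) / 2
  cz <- if (is.null(z_center))
    (max(tree$nodes$z) + min(tree$nodes$z)) / 2 else z_center
  u <- cos(th) * (tree$nodes$x - cx) + sin(th) * (tree$nodes$z - cz)
  px <- round(u + cx) + 1L
  py <- round(tree$nodes$y) + 1L
  img <- matrix(NA_real_, dims[1], dims[2])
  ok <- px >= 1 & px <= dims[1] & py >= 1 & py <= dims[2]
  off <- if (dilate) expand.grid(dx = -1:1, dy = -1:1) else
    data.frame(dx = 0, dy = 0)
  for (o in seq_len(nrow(off))) {
    qx <- px[ok] + off$dx[o]; qy <- py[ok] + off$dy[o]
    sel <- qx >= 1 & qx <= dims[1] & qy >= 1 & qy <= dims[2]
    idx <- cbind(qx[sel], qy[sel])
    v <- vals[ok][sel]
    cur <- img[idx]
    img[idx] <- ifelse(is.na(cur), v, pmax(cur, v))
    # resolve collisions within this batch (multiple nodes, same pixel)
    dup <- duplicated(idx) | duplicated(idx, fromLast = TRUE)
    if (any(dup)) {
      key <- paste(idx[dup, 1], idx[dup, 2])
      mx <- tapply(v[dup], key, max)
      kidx <- do.call(rbind, lapply(strsplit(names(mx), " "), as.integer))
      img[kidx] <- pmax(img[kidx], as.numeric(mx), na.rm = TRUE)
    }
  }
  structure(list(pixels = img, view_angle = a, pixel_size = pixel_size,
                 kind = "attribute"),
            class = "projection2d")
}

#' @export
print.projection2d <- function(x, ...) {
  cat(sprintf("<projection2d:%s> %d x %d px, angle %.1f deg, %.4g mm/px\n",
              x$kind, nrow(x$pixels), ncol(x$pixels), x$view_angle,
              x$pixel_size))
  invisible(x)
}
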