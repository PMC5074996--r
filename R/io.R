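#' Read a 3D intensity volume
#'
#' Supported containers: NIfTI (`.nii` / `.nii.gz`, voxel size from the
#' header), multi-page TIFF (`.tif` / `.tiff`, voxel size and intensity
#' scaling from the mandatory JSON sidecar `<path>.json`), and raw binary
#' (`.raw`, little-endian float64 with a JSON sidecar giving `dims` and
#' `voxel_size_mm`). A voxel size is always required and must be isotropic:
#' the caliber method assumes isotropic voxels.
#'
#' @param path file path.
#' @return an [intensity_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)[1:3]
    if (max(pd) - min(pd) > 1e-6 * max(pd))
      stop("non-isotropic voxels (", paste(signif(pd, 4), collapse = " x "),
           " mm): the method assumes isotropy")
    if (pd[1] <= 0) stop("missing voxel size in NIfTI header")
    return(intensity_volume(array(as.numeric(img), dim = dim(img)), pd[1]))
  }
  if (grepl("\\.tiff?$", low)) {
    side <- read_sidecar(path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    vox <- simplify2array(pages)            # (x, y, z)
    vox <- vox * side$intensity_scale + side$intensity_offset
    return(intensity_volume(vox, side$voxel_size_mm))
  }
  if (grepl("\\.raw$", low)) {
    side <- read_sidecar(path)
    n <- prod(side$dims)
    v <- readBin(path, "double", n = n, size = 8, endian = "little")
    return(intensity_volume(array(v, dim = side$dims), side$voxel_size_mm))
  }
  stop("unrecognized volume format: ", path)
}

read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc))
    stop("missing JSON sidecar ", sc,
         " (voxel size is required; there is no silent default)")
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(side$voxel_size_mm) || side$voxel_size_mm <= 0)
    stop("sidecar ", sc, " lacks a positive voxel_size_mm")
  if (is.null(side$intensity_scale)) side$intensity_scale <- 1
  if (is.null(side$intensity_offset)) side$intensity_offset <- 0
  side
}

#' Write a 3D intensity volume
#'
#' Format from the extension (see [read_volume()]). TIFF pages are stored
#' as 32-bit float rescaled to `[0, 1]`; the scale/offset needed to recover
#' the original intensities, the voxel size, and any provenance parameters
#' are written to the JSON sidecar `<path>.json` (NIfTI gets a sidecar too,
#' for provenance only).
#'
#' @param vol an [intensity_volume()] or 3D array.
#' @param path output path (`.nii`, `.nii.gz`, `.tif`, or `.raw`).
#' @param provenance optional named list echoed into the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, provenance = NULL) {
  vol <- as_volume(vol)
  low <- tolower(path)
  side <- list(voxel_size_mm = vol$voxel_size, dims = dim(vol$voxels),
               written_by = paste0("vesselcal ",
                                   as.character(utils::packageVersion("vesselcal"))),
               parameters = provenance)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- RNifti::asNifti(vol$voxels)
    RNifti::pixdim(img) <- rep(vol$voxel_size, 3)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", low)) {
    rng <- range(vol$voxels)
    scl <- if (diff(rng) > 0) diff(rng) else 1
    side$intensity_scale <- scl
    side$intensity_offset <- rng[1]
    norm <- (vol$voxels - rng[1]) / scl
    pages <- lapply(seq_len(dim(norm)[3]), function(k) norm[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else if (grepl("\\.raw$", low)) {
    writeBin(as.numeric(vol$voxels), path, size = 8, endian = "little")
  } else {
    stop("unrecognized volume format: ", path)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a 2D projection image
#'
#' 32-bit float TIFF rescaled to `[0, 1]`, with view angle, pixel size and
#' intensity scaling in the JSON sidecar. `NA` background pixels are
#' written as the image minimum and flagged in the sidecar.
#'
#' @param proj a `projection2d`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(proj, path) {
  stopifnot(inherits(proj, "projection2d"))
  px <- proj$pixels
  na_bg <- anyNA(px)
  if (na_bg) px[is.na(px)] <- min(px, na.rm = TRUE)
  rng <- range(px)
  scl <- if (diff(rng) > 0) diff(rng) else 1
  tiff::writeTIFF((px - rng[1]) / scl, path, bits.per.sample = 32L)
  jsonlite::write_json(list(view_angle_deg = proj$view_angle,
                            pixel_size_mm = proj$pixel_size,
                            kind = proj$kind, intensity_scale = scl,
                            intensity_offset = rng[1],
                            na_background = na_bg),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

tree_parents <- function(tree) {
  g <- tree_graph(tree)
  n <- nrow(tree$nodes)
  root <- if (is.na(tree$root)) 1L else tree$root
  parent <- rep(NA_integer_, n)
  comps <- igraph::components(g)
  for (cm in seq_len(comps$no)) {
    members <- which(comps$membership == cm)
    r <- if (root %in% members) root else members[1]
    bfs <- igraph::bfs(g, root = r, unreachable = FALSE, father = TRUE)
    f <- as.integer(bfs$father)[members]
    parent[members] <- ifelse(is.na(f) | f == 0L, -1L, f)
    parent[r] <- -1L
  }
  parent
}

#' Write a centerline tree
#'
#' SWC: one record per node (`id type x y z radius parent`), coordinates
#' in mm (voxel coordinate times voxel size, origin at the volume corner),
#' radius = `d_ct / 2` in mm when set, else 0. SWC requires an acyclic
#' graph. CSV: `<path>_nodes.csv` and `<path>_edges.csv` preserving all
#' node attributes.
#'
#' @param tree a `centerline_tree`.
#' @param path output path; for CSV this is a prefix.
#' @param format `"swc"` or `"csv"`.
#' @param voxel_size mm per voxel used to convert coordinates.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path, format = c("swc", "csv"),
                       voxel_size = 1) {
  format <- match.arg(format)
  stopifnot(inherits(tree, "centerline_tree"))
  if (format == "swc") {
    g <- tree_graph(tree)
    if (igraph::ecount(g) > igraph::vcount(g) - igraph::components(g)$no)
      stop("cyclic graph cannot be written as SWC")
    parent <- tree_parents(tree)
    rad <- ifelse(is.na(tree$nodes$d_ct), 0, tree$nodes$d_ct / 2)
    rec <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                   tree$nodes$id, 0L,
                   tree$nodes$x * voxel_size, tree$nodes$y * voxel_size,
                   tree$nodes$z * voxel_size, rad, parent)
    writeLines(c("# SWC centerline tree (coordinates in mm)",
                 sprintf("# voxel_size_mm %g", voxel_size), rec), path)
  } else {
    nd <- tree$nodes
    nd$generation <- node_generations(tree)
    write.csv(nd, paste0(path, "_nodes.csv"), row.names = FALSE)
    write.csv(tree$edges, paste0(path, "_edges.csv"), row.names = FALSE)
  }
  invisible(path)
}

node_generations <- function(tree) {
  gen <- rep(NA_integer_, nrow(tree$nodes))
  for (b in seq_along(tree$branches))
    gen[tree$branches[[b]]] <- tree$branch_generation[b]
  gen
}

#' Read a centerline tree written by [write_tree()]
#'
#' @param path SWC file, or the CSV prefix used when writing.
#' @param format `"swc"` or `"csv"`.
#' @param voxel_size mm per voxel (to convert SWC mm back to voxels).
#' @return a `centerline_tree`.
#' @export
read_tree <- function(path, format = c("swc", "csv"), voxel_size = 1) {
  format <- match.arg(format)
  if (format == "swc") {
    ln <- readLines(path)
    ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
    m <- do.call(rbind, lapply(strsplit(trimws(ln), "\\s+"), as.numeric))
    nodes <- data.frame(id = as.integer(m[, 1]),
                        x = m[, 3] / voxel_size, y = m[, 4] / voxel_size,
                        z = m[, 5] / voxel_size, s_max = NA_real_,
                        d_ct = ifelse(m[, 6] > 0, 2 * m[, 6], NA_real_))
    par <- as.integer(m[, 7])
    has_par <- par > 0
    edges <- data.frame(from = par[has_par], to = nodes$id[has_par])
  } else {
    nodes <- read.csv(paste0(path, "_nodes.csv"))
    nodes$generation <- NULL
    edges <- read.csv(paste0(path, "_edges.csv"))
  }
  tree <- structure(list(nodes = nodes, edges = edges, branches = list(),
                         branch_generation = integer(0),
                         root = NA_integer_),
                    class = "centerline_tree")
  rebuild_branches(tree)
}
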