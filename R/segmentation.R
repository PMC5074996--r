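#' Seeded flood-fill segmentation of the probability volume
#'
#' Grows 26-connected regions from the seed voxels through all voxels whose
#' vesselness probability is at least `threshold`.
#'
#' @param prob probability volume: a `vesselness_result`, 3D array, or
#'   [intensity_volume()].
#' @param seeds matrix (or vector) of 1-based voxel coordinates, one seed
#'   per row; every seed must itself reach the threshold.
#' @param threshold probability cutoff in `[0, 1]`; 0.05 by default (the
#'   vesselness output is sparse and high-contrast).
#' @return A `vessel_mask`: list with logical array `voxels`, `seed_points`
#'   and `threshold`.
#' @export
flood_fill_segment <- function(prob, seeds, threshold = 0.05) {
  prob <- probability_of(prob)
  d <- dim(prob)
  seeds <- matrix(as.integer(round(seeds)), ncol = 3)
  if (any(seeds < 1) || any(seeds > matrix(d, nrow(seeds), 3, byrow = TRUE)))
    stop("seed outside the volume")
  pv <- prob[seeds]
  if (any(pv < threshold))
    stop(sprintf("seed (%s) has probability %.4g below threshold %.4g",
                 paste(seeds[which(pv < threshold)[1], ], collapse = ", "),
                 min(pv), threshold))
  m <- cpp_flood_fill(as.numeric(prob), d, seeds - 1L, threshold)
  structure(list(voxels = array(m, dim = d), seed_points = seeds,
                 threshold = threshold),
            class = "vessel_mask")
}

probability_of <- function(x) {
  if (inherits(x, "vesselness_result")) return(x$probability)
  if (inherits(x, "intensity_volume")) return(x$voxels)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected a vesselness_result, intensity_volume, or 3D array")
}

mask_of <- function(x) {
  if (inherits(x, "vessel_mask")) return(x$voxels)
  if (is.array(x) && length(dim(x)) == 3L) return(x != 0)
  stop("expected a vessel_mask or 3D array")
}

#' Skeletonize a vessel mask to a centerline tree
#'
#' Thins the mask to a unit-width 26-connected skeleton by sequential
#' topology-preserving thinning (six directional subiterations per pass;
#' a voxel is removed only if it is a simple point and not a curve
#' endpoint), converts the skeleton voxels to a graph, breaks any remaining
#' cycles by dropping the lowest-probability edge per cycle, prunes short
#' terminal spurs, decomposes the result into branches (maximal paths
#' between junctions/endpoints) and assigns branch generations from a root.
#'
#' @param mask a `vessel_mask` from [flood_fill_segment()] or a logical 3D
#'   array; must be non-empty.
#' @param prob optional probability volume used to weight edges when
#'   breaking cycles (higher-probability edges are kept).
#' @param prune_spurs remove thinning spurs (default on): terminal
#'   branches are dropped when they are shorter than `spur_min_nodes`
#'   nodes, or when their tip does not reach beyond the locally inscribed
#'   mask radius at the junction they hang off. Iterative thinning of a
#'   thick structure protects every transient curve endpoint, so each
#'   surface bump grows a radial spur about one local radius long; a real
#'   side branch, by contrast, extends past its parent's inscribed sphere.
#' @param spur_min_nodes minimum node count for a terminal branch.
#' @param root optional node id to use as tree root; by default the
#'   endpoint with the largest mapped `s_max` (when available, else the
#'   first endpoint).
#' @return A `centerline_tree`: list with data frames `nodes`
#'   (id, x, y, z in 0-based voxel coordinates, plus attribute columns) and
#'   `edges` (from, to), a list `branches` of node-id paths, integer
#'   `branch_generation`, and `root`.
#' @export
skeletonize <- function(mask, prob = NULL, prune_spurs = TRUE,
                        spur_min_nodes = 3, root = NULL) {
  mv <- mask_of(mask)
  d <- dim(mv)
  if (!any(mv)) stop("mask is empty")
  sk <- array(cpp_thin3d(as.logical(mv), d), dim = d)
  idx <- which(sk)
  coords <- arrayInd(idx, d) - 1L
  nid <- integer(prod(d))
  nid[idx] <- seq_along(idx)
  # edges: 13 positive neighbour offsets (26-connectivity, no duplicates)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 1] + 3 * offs[, 2] + 9 * offs[, 3] > 0, , drop = FALSE]
  ef <- integer(0); et <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[o, ], nrow(coords), 3, byrow = TRUE)
    ok <- nb[, 1] >= 0 & nb[, 1] < d[1] & nb[, 2] >= 0 & nb[, 2] < d[2] &
      nb[, 3] >= 0 & nb[, 3] < d[3]
    lin <- 1L + nb[ok, 1] + d[1] * (nb[ok, 2] + d[2] * nb[ok, 3])
    tgt <- nid[lin]
    src <- which(ok)[tgt > 0]
    ef <- c(ef, src); et <- c(et, tgt[tgt > 0])
  }
  g <- igraph::graph_from_edgelist(cbind(ef, et), directed = FALSE)
  if (igraph::vcount(g) < length(idx))
    g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
  # break cycles: maximum-probability spanning forest
  if (igraph::ecount(g) >= igraph::vcount(g)) {
    pr <- if (is.null(prob)) NULL else probability_of(prob)
    w <- if (is.null(pr)) rep(1, igraph::ecount(g)) else {
      pe <- pmin(pr[idx[ef]], pr[idx[et]])
      1 - pe
    }
    g <- igraph::mst(g, weights = w)
  }
  nodes <- data.frame(id = seq_along(idx), x = coords[, 1], y = coords[, 2],
                      z = coords[, 3], s_max = NA_real_, d_ct = NA_real_)
  el <- igraph::as_edgelist(g)
  tree <- structure(list(nodes = nodes,
                         edges = data.frame(from = as.integer(el[, 1]),
                                            to = as.integer(el[, 2])),
                         branches = list(), branch_generation = integer(0),
                         root = NA_integer_),
                    class = "centerline_tree")
  if (prune_spurs) tree <- prune_spur_branches(tree, mv, spur_min_nodes)
  tree <- rebuild_branches(tree, root = root)
  tree
}

# distance from a voxel (0-based coords) to the nearest background voxel
local_mask_radius <- function(mask, p) {
  d <- dim(mask)
  w <- 4L
  repeat {
    lo <- pmax(p - w, 0L); hi <- pmin(p + w, d - 1L)
    sub <- mask[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L,
                drop = FALSE]
    bg <- which(!sub)
    if (length(bg) > 0) {
      co <- arrayInd(bg, dim(sub))
      dx <- co[, 1] - 1L + lo[1] - p[1]
      dy <- co[, 2] - 1L + lo[2] - p[2]
      dz <- co[, 3] - 1L + lo[3] - p[3]
      return(sqrt(min(dx^2 + dy^2 + dz^2)))
    }
    if (all(lo == 0L) && all(hi == d - 1L)) return(Inf)
    w <- w * 2L
  }
}

# Iteratively remove terminal branches that are thinning artifacts: those
# shorter than spur_min_nodes, and those whose tip stays within ~one locally
# inscribed radius of the junction they are attached to.
prune_spur_branches <- function(tree, mask, spur_min_nodes) {
  repeat {
    tree <- rebuild_branches(tree)
    g <- tree_graph(tree)
    deg <- igraph::degree(g)
    drop <- integer(0)
    for (b in seq_along(tree$branches)) {
      path <- tree$branches[[b]]
      d1 <- deg[path[1]]; d2 <- deg[path[length(path)]]
      if (xor(d1 == 1L, d2 == 1L)) {        # terminal branch off a junction
        if (d1 == 1L) { tip <- path[1]; junc <- path[length(path)] }
        else { tip <- path[length(path)]; junc <- path[1] }
        body <- setdiff(path, junc)
        if (length(body) == 0) next
        if (length(body) < spur_min_nodes) { drop <- c(drop, body); next }
        pj <- as.integer(round(unlist(
          tree$nodes[tree$nodes$id == junc, c("x", "y", "z")])))
        r_loc <- local_mask_radius(mask, pj)
        pt <- unlist(tree$nodes[tree$nodes$id == tip, c("x", "y", "z")])
        reach <- sqrt(sum((pt - pj)^2))
        if (is.finite(r_loc) && reach <= 1.3 * r_loc + 2)
          drop <- c(drop, body)
      }
    }
    drop <- unique(drop)
    if (length(drop) == 0) return(tree)
    tree <- drop_tree_nodes(tree, drop)
  }
}

tree_graph <- function(tree) {
  g <- igraph::graph_from_edgelist(as.matrix(tree$edges), directed = FALSE)
  n <- nrow(tree$nodes)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

drop_tree_nodes <- function(tree, drop) {
  keep <- setdiff(tree$nodes$id, drop)
  remap <- integer(max(tree$nodes$id))
  remap[keep] <- seq_along(keep)
  nodes <- tree$nodes[tree$nodes$id %in% keep, , drop = FALSE]
  nodes$id <- remap[nodes$id]
  ed <- tree$edges[tree$edges$from %in% keep & tree$edges$to %in% keep, ,
                   drop = FALSE]
  ed$from <- remap[ed$from]; ed$to <- remap[ed$to]
  rownames(nodes) <- NULL
  tree$nodes <- nodes
  tree$edges <- ed
  tree
}

# decompose into maximal degree-<=2 paths and assign generations by BFS
# over branches starting from the root's branch
rebuild_branches <- function(tree, root = NULL) {
  g <- tree_graph(tree)
  deg <- igraph::degree(g)
  n <- nrow(tree$nodes)
  breakpoints <- which(deg != 2L)
  branches <- list()
  visited_edge <- new.env(hash = TRUE)
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  adj <- igraph::as_adj_list(g)
  walk <- function(start, nxt) {
    path <- c(start, nxt)
    prev <- start; cur <- nxt
    while (deg[cur] == 2L) {
      nb <- setdiff(as.integer(adj[[cur]]), prev)
      if (length(nb) == 0L) break
      prev <- cur; cur <- nb[1]
      path <- c(path, cur)
    }
    path
  }
  starts <- breakpoints
  if (length(starts) == 0L && n > 0L) starts <- 1L  # pure cycle fallback
  for (s in starts) {
    for (nb in as.integer(adj[[s]])) {
      k <- ekey(s, nb)
      if (!is.null(visited_edge[[k]])) next
      path <- walk(s, nb)
      for (i in seq_len(length(path) - 1))
        visited_edge[[ekey(path[i], path[i + 1])]] <- TRUE
      branches[[length(branches) + 1]] <- path
    }
  }
  # deduplicate paths traversed from both ends
  if (length(branches) > 1) {
    keep <- !duplicated(vapply(branches, function(p)
      paste(sort(p), collapse = "_"), character(1)))
    branches <- branches[keep]
  }
  tree$branches <- branches
  # root: endpoint with largest s_max attribute if present
  if (is.null(root)) {
    eps <- which(deg == 1L)
    if (length(eps) == 0L) eps <- seq_len(n)
    sm <- tree$nodes$s_max[eps]
    root <- if (any(!is.na(sm))) eps[which.max(sm)] else eps[1]
  }
  tree$root <- as.integer(root)
  tree$branch_generation <- branch_generations(tree)
  tree
}

branch_generations <- function(tree) {
  nb <- length(tree$branches)
  if (nb == 0L) return(integer(0))
  gen <- rep(NA_integer_, nb)
  ends <- lapply(tree$branches, function(p) c(p[1], p[length(p)]))
  # branches touching the root's branch chain get generation 1, etc.
  touch_root <- vapply(tree$branches, function(p) tree$root %in% p, logical(1))
  if (!any(touch_root)) touch_root[1] <- TRUE
  gen[touch_root] <- 1L
  frontier <- which(touch_root)
  claimed_nodes <- unique(unlist(tree$branches[frontier]))
  while (length(frontier) > 0) {
    nxt <- integer(0)
    newly <- integer(0)
    for (b in seq_len(nb)) {
      if (!is.na(gen[b])) next
      if (any(ends[[b]] %in% claimed_nodes)) {
        gb <- min(gen[frontier[vapply(frontier, function(fb)
          any(ends[[b]] %in% tree$branches[[fb]]), logical(1))]])
        gen[b] <- gb + 1L
        nxt <- c(nxt, b)
        newly <- c(newly, tree$branches[[b]])
      }
    }
    if (length(nxt) == 0) break
    claimed_nodes <- unique(c(claimed_nodes, newly))
    frontier <- nxt
  }
  gen[is.na(gen)] <- 1L  # disconnected components restart at 1
  gen
}

#' Map a 3D field onto centerline tree nodes
#'
#' Samples `field` at each node coordinate (nearest voxel) and stores the
#' values as a node attribute. Re-mapping the same field is idempotent.
#'
#' @param tree a `centerline_tree`.
#' @param field 3D array (or `vesselness_result` for `name = "s_max"`)
#'   covering all node coordinates.
#' @param name attribute label, e.g. `"s_max"` or `"d_ct"`.
#' @param reroot when mapping `s_max`, recompute the root (largest-S_MAX
#'   endpoint) and branch generations (default `TRUE`).
#' @return the tree with `nodes[[name]]` filled in.
#' @export
map_attribute_to_tree <- function(tree, field, name, reroot = TRUE) {
  stopifnot(inherits(tree, "centerline_tree"))
  if (inherits(field, "vesselness_result"))
    field <- if (identical(name, "probability")) field$probability else field$s_max
  d <- dim(field)
  ix <- tree$nodes$x + 1L; iy <- tree$nodes$y + 1L; iz <- tree$nodes$z + 1L
  if (any(ix < 1 | ix > d[1] | iy < 1 | iy > d[2] | iz < 1 | iz > d[3]))
    stop("tree node outside the field")
  tree$nodes[[name]] <- field[cbind(ix, iy, iz)]
  if (identical(name, "s_max") && reroot) tree <- rebuild_branches(tree)
  tree
}

#' @export
print.centerline_tree <- function(x, ...) {
  cat(sprintf("<centerline_tree> %d nodes, %d edges, %d branches\n",
              nrow(x$nodes), nrow(x$edges), length(x$branches)))
  if (length(x$branch_generation))
    cat(sprintf("  generations 1..%d; root node %d\n",
                max(x$branch_generation), x$root))
  invisible(x)
}
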