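#' Save / load a calibration model as JSON
#'
#' @param model a `calibration_model`.
#' @param path JSON file path.
#' @return `path` (save) or the model (load).
#' @export
save_calibration_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(list(slope = model$slope, intercept = model$intercept,
                            r = model$r, n_points = model$n_points,
                            points = model$points),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_calibration_model
#' @export
read_calibration_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slope = j$slope, intercept = j$intercept, r = j$r,
                 n_points = j$n_points, slope_inverse = 1 / j$slope,
                 points = j$points),
            class = "calibration_model")
}

#' Match centerline branches to ground-truth tree segments
#'
#' For each branch, the node nearest the branch midpoint is matched to the
#' ground-truth segment whose tube surface is closest (point-to-segment
#' distance minus the segment radius, so a point is matched to the segment
#' that contains it rather than to a thinner neighbor whose axis happens
#' to pass nearby — the distinction matters near junctions). The signed
#' surface distance is reported; values <= 0 mean the midpoint lies inside
#' the matched tube.
#'
#' @param tree a `centerline_tree` with `d_ct` mapped (any unit).
#' @param segments ground-truth data frame as produced by
#'   [generate_tree_volume()] (`ground_truth$segments`), in voxel units.
#' @param summary_stat how to summarize `d_ct` over the interior nodes of a
#'   branch (`median` by default).
#' @return data frame with one row per branch: `branch`, `generation`,
#'   `n_nodes`, `d_ct` (branch summary over interior nodes),
#'   `truth_diameter`, `match_distance` (midpoint to matched axis),
#'   `surface_distance` (signed; <= 0 means inside the matched tube),
#'   `containment` (fraction of interior nodes inside the matched tube;
#'   low values mark skeleton artifacts that follow no segment), and
#'   `midpoint_d_ct`.
#' @export
match_branches_to_truth <- function(tree, segments,
                                    summary_stat = stats::median) {
  stopifnot(inherits(tree, "centerline_tree"))
  seg_d <- function(p) {
    a <- as.matrix(segments[, c("x0", "y0", "z0")])
    b <- as.matrix(segments[, c("x1", "y1", "z1")])
    ab <- b - a
    ap <- matrix(p, nrow(a), 3, byrow = TRUE) - a
    t <- rowSums(ap * ab) / rowSums(ab^2)
    t <- pmin(pmax(t, 0), 1)
    sqrt(rowSums((ap - ab * t)^2))
  }
  rows <- lapply(seq_along(tree$branches), function(b) {
    ids <- tree$branches[[b]]
    # interior nodes only: junction voxels mix neighboring calibers
    inner <- if (length(ids) > 4) ids[3:(length(ids) - 2)] else ids
    mid <- ids[ceiling(length(ids) / 2)]
    p <- as.numeric(tree$nodes[tree$nodes$id == mid, c("x", "y", "z")])
    dd <- seg_d(p)
    surf <- dd - segments$diameter / 2
    j <- which.min(surf)
    # containment: fraction of interior nodes inside the matched tube
    nin <- tree$nodes[tree$nodes$id %in% inner, c("x", "y", "z")]
    insd <- vapply(seq_len(nrow(nin)), function(k) {
      s <- seg_d(as.numeric(nin[k, ]))
      s[j] - segments$diameter[j] / 2 <= 1
    }, logical(1))
    data.frame(branch = b, generation = tree$branch_generation[b],
               n_nodes = length(ids),
               d_ct = summary_stat(tree$nodes$d_ct[tree$nodes$id %in% inner],
                                   na.rm = TRUE),
               truth_diameter = segments$diameter[j],
               match_distance = dd[j],
               surface_distance = surf[j],
               containment = mean(insd),
               midpoint_d_ct = tree$nodes$d_ct[tree$nodes$id == mid])
  })
  do.call(rbind, rows)
}

#' Run the full contrast-free caliber pipeline
#'
#' Executes vesselness -> flood-fill segmentation -> skeletonization ->
#' S_MAX mapping -> D_CT conversion -> forward projection -> report.
#' Every stage logs its parameters; artifacts and a JSON provenance
#' sidecar are written to `out_dir` when one is given. The run is
#' deterministic for a fixed configuration.
#'
#' @param config a named list (or path to a YAML file) with elements:
#'   `input` (path to a volume) or `volume` (an [intensity_volume()]);
#'   `vesselness` (arguments for [vesselness_params()]); `seeds` (matrix of
#'   1-based seed voxels; default: the global probability maximum);
#'   `threshold` (flood-fill cutoff, default 0.05); `calibration_model`
#'   (path to a model JSON or a `calibration_model`); `voxel_size_mm`
#'   (required if the volume does not carry one); `angles` (projection
#'   views, default 0); `out_dir` (optional output directory);
#'   `verbose` (default `TRUE`).
#' @return list with the vesselness result, mask, tree (with `s_max` and
#'   `d_ct`), projections, and the per-branch `report` data frame (plus a
#'   ground-truth comparison when the input is a tree phantom).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  say <- function(...) if (isTRUE(config$verbose %||% TRUE))
    message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  vol <- stage("input", {
    if (!is.null(config$volume)) as_volume(config$volume,
                                           config$voxel_size_mm %||% 1)
    else if (!is.null(config$input)) read_volume(config$input)
    else stop("config needs `input` (path) or `volume` (object)")
  })
  if (!is.null(config$voxel_size_mm)) vol$voxel_size <- config$voxel_size_mm
  model <- stage("calibration model", {
    cm <- config$calibration_model
    if (is.null(cm))
      stop("no calibration model configured; fit one with ",
           "calibrate_phantom() and pass its JSON path or the object ",
           "as `calibration_model`")
    if (inherits(cm, "calibration_model")) cm else read_calibration_model(cm)
  })
  params <- stage("vesselness parameters",
                  do.call(vesselness_params, config$vesselness %||% list()))
  say("vesselness: %s scales on %s volume",
      length(params$scales), paste(dim(vol$voxels), collapse = "x"))
  vr <- stage("vesselness", multiscale_vesselness(vol, params))
  threshold <- config$threshold %||% 0.05
  seeds <- config$seeds
  if (is.null(seeds)) {
    seeds <- arrayInd(which.max(vr$probability), dim(vr$probability))
    say("seed: global probability maximum at (%s)",
        paste(seeds, collapse = ", "))
  }
  say("flood fill at threshold %.3g", threshold)
  mask <- stage("segmentation", flood_fill_segment(vr, seeds, threshold))
  say("skeletonize %d mask voxels", sum(mask$voxels))
  tree <- stage("skeletonization", skeletonize(mask, prob = vr))
  tree <- stage("attribute mapping", map_attribute_to_tree(tree, vr, "s_max"))
  say("convert S_MAX to D_CT (slope %.4f, intercept %.4f, voxel %.4g mm)",
      model$slope, model$intercept, vol$voxel_size)
  tree$nodes$d_ct <- stage("caliber conversion",
                           smax_to_diameter(tree$nodes$s_max, model,
                                            vol$voxel_size))
  angles <- config$angles %||% 0
  projections <- stage("projection", lapply(angles, function(a) {
    list(intensity = max_intensity_project(vol, a),
         d_ct = project_tree_attribute(
           tree, "d_ct", a, dim(vol$voxels)[1:2],
           z_center = (dim(vol$voxels)[3] - 1) / 2))
  }))
  report <- stage("report", {
    rep <- data.frame(branch = seq_along(tree$branches),
                      generation = tree$branch_generation,
                      n_nodes = lengths(tree$branches),
                      s_max = vapply(tree$branches, function(ids)
                        median(tree$nodes$s_max[tree$nodes$id %in% ids],
                               na.rm = TRUE), numeric(1)))
    rep$d_ct_mm <- smax_to_diameter(rep$s_max, model, vol$voxel_size)
    gt <- vol$ground_truth
    if (!is.null(gt) && identical(gt$kind, "tree")) {
      cmp <- match_branches_to_truth(tree, gt$segments)
      rep$truth_diameter_mm <- cmp$truth_diameter * vol$voxel_size
      rep$d_ct_branch_mm <- cmp$d_ct
      rep$rel_error <- (cmp$d_ct - rep$truth_diameter_mm) /
        rep$truth_diameter_mm
    }
    rep
  })
  out <- list(vesselness = vr, mask = mask, tree = tree,
              projections = projections, report = report, model = model,
              params = params)
  if (!is.null(config$out_dir)) stage("output", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- list(vesselness = config$vesselness, threshold = threshold,
                 seeds = seeds, angles = angles,
                 voxel_size_mm = vol$voxel_size,
                 model = list(slope = model$slope,
                              intercept = model$intercept))
    write_volume(intensity_volume(vr$probability, vol$voxel_size),
                 file.path(config$out_dir, "probability.nii.gz"), prov)
    sm <- vr$s_max; sm[is.na(sm)] <- 0
    write_volume(intensity_volume(sm, vol$voxel_size),
                 file.path(config$out_dir, "s_max.nii.gz"), prov)
    write_volume(intensity_volume(mask$voxels + 0, vol$voxel_size),
                 file.path(config$out_dir, "mask.nii.gz"), prov)
    write_tree(tree, file.path(config$out_dir, "tree.swc"),
               voxel_size = vol$voxel_size)
    write_tree(tree, file.path(config$out_dir, "tree"), format = "csv")
    for (i in seq_along(projections)) {
      write_projection(projections[[i]]$intensity,
                       file.path(config$out_dir,
                                 sprintf("mip_%03d.tif", round(angles[i]))))
    }
    write.csv(report, file.path(config$out_dir, "report.csv"),
              row.names = FALSE)
    jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  say("pipeline complete: %d branches reported", nrow(report))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
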