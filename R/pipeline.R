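#' Pipeline configuration
#'
#' Bundles every tunable of the reconstruction pipeline. The two headline
#' knobs keep their conventional defaults: `hs = 0.5` (the geodesic
#' bin length, m — "height segmentation") and `cp = 0.003` (the voxel
#' thinning edge, m — "cloud parameter"). For synthetic fixtures a much
#' smaller `hs` (0.02-0.05 m) is appropriate: meter-scale bins would
#' collapse a ~2 m root system into a handful of nodes.
#'
#' @param hs geodesic bin length (m) used by [extract_skeleton()].
#' @param cp voxel thinning edge (m) used by [downsample_cp()]; 0 disables.
#' @param knn_k neighbours per point in the graph.
#' @param denoise_k,denoise_std statistical outlier removal parameters.
#' @param continuation rule for which child chain continues a branch at a
#'   bifurcation: `"largest_radius"` (default) or `"longest_path"`.
#' @param slab_thickness,n_slabs basal-diameter slab geometry
#'   (see [basal_diameter()]).
#' @param min_basal_diameter_cm coarse-root counting threshold (cm).
#' @param prune_min_length drop childless branches shorter than this (m)
#'   after order assignment; 0 disables. Mirrors the field protocol of
#'   clipping stub roots.
#' @param anchor_collar start the geodesic field from a synthetic
#'   collar-center anchor (see [anchor_collar()]) instead of a surface
#'   vertex.
#' @param seed integer seed recorded in manifests and used wherever a stage
#'   needs randomness.
#' @return an object of class `root_config` (a named list).
#' @export
root_config <- function(hs = 0.5, cp = 0.003, knn_k = 10, denoise_k = 8,
                        denoise_std = 2.0,
                        continuation = c("largest_radius", "longest_path"),
                        slab_thickness = 0.01, n_slabs = 3,
                        min_basal_diameter_cm = 0.5,
                        prune_min_length = 0.05, anchor_collar = TRUE,
                        seed = 1) {
  structure(list(
    hs = hs, cp = cp, knn_k = as.integer(knn_k),
    denoise_k = as.integer(denoise_k), denoise_std = denoise_std,
    continuation = match.arg(continuation),
    slab_thickness = slab_thickness, n_slabs = as.integer(n_slabs),
    min_basal_diameter_cm = min_basal_diameter_cm,
    prune_min_length = prune_min_length,
    anchor_collar = isTRUE(anchor_collar), seed = as.integer(seed)
  ), class = "root_config")
}

#' @export
print.root_config <- function(x, ...) {
  cat("<root_config>\n")
  for (nm in names(x)) cat("  ", nm, ": ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Run the full reconstruction pipeline on a cloud
#'
#' Optional inversion, statistical denoising, CP voxel thinning, k-NN graph,
#' collar selection, Dijkstra shortest-path tree, geodesic-bin skeleton,
#' cylinder fitting, bottom-up order assignment and stub pruning — one call.
#'
#' @param data a cloud tibble.
#' @param config a [root_config()].
#' @param invert flip the vertical axis first (collar-up field scans).
#' @param denoise run statistical outlier removal.
#' @return a list with `cloud` (the processed cloud the model refers to),
#'   `graph`, `spt`, `skeleton`, `model` and `config`.
#' @export
reconstruct_root <- function(data, config = root_config(), invert = FALSE,
                             denoise = TRUE) {
  data <- as_cloud(data)
  if (invert) data <- invert_axis(data)
  if (denoise) {
    data <- remove_outliers(data, k = config$denoise_k,
                            std_ratio = config$denoise_std)
  }
  data <- downsample_cp(data, cp = config$cp)
  if (config$anchor_collar) {
    anch <- anchor_collar(data)
    data <- anch$cloud
    src <- anch$index
    graph <- build_neighbor_graph(data, k = config$knn_k)
    graph <- add_source_edges(graph, data, src, anch$slab)
  } else {
    src <- select_root_vertex(data)
    graph <- build_neighbor_graph(data, k = config$knn_k)
  }
  spt <- shortest_path_tree(graph, src)
  skeleton <- extract_skeleton(data, spt, bin_length = config$hs)
  model <- model_from_skeleton(data, skeleton)
  model <- assign_orders(model, continuation = config$continuation)
  if (config$prune_min_length > 0) {
    model <- prune_model(model, min_length = config$prune_min_length)
  }
  list(cloud = data, graph = graph, spt = spt, skeleton = skeleton,
       model = model, config = config)
}

#' Remove short childless stub branches
#'
#' Iteratively drops branches that have no children and whose total length
#' is below `min_length`; such stubs are usually noise or junction
#' artifacts, the digital analogue of clipping stub roots in the field.
#' The taproot is never pruned.
#'
#' @param model a `root_model` with orders assigned.
#' @param min_length threshold (m).
#' @return the pruned model.
#' @export
prune_model <- function(model, min_length) {
  stopifnot(inherits(model, "root_model"))
  if (is.null(model$branches)) abort("prune_model: assign orders first.")
  repeat {
    br <- model$branches
    cyl <- model$cylinders
    has_child <- br$branch_id %in% br$parent_branch
    # ghost stubs: 1-2 cylinder dead ends as thick as the root they sit on
    # are severed ring arcs from the skeletonization, not real laterals
    parent_r <- vapply(seq_len(nrow(br)), function(i) {
      j <- which((cyl$to_node == br$attach_node[i] |
                    cyl$from_node == br$attach_node[i]) &
                 cyl$branch_id == br$parent_branch[i])
      if (length(j)) max(cyl$radius[j]) else NA_real_
    }, numeric(1))
    min_r <- vapply(br$branch_id, function(b) {
      suppressWarnings(min(cyl$radius[cyl$branch_id == b], na.rm = TRUE))
    }, numeric(1))
    ghost <- !has_child & br$order > 0 & br$n_cylinders <= 3 &
      is.finite(parent_r) & min_r >= 0.7 * parent_r
    drop <- br$branch_id[(!has_child & br$length < min_length & br$order > 0) |
                           ghost]
    if (length(drop) == 0) break
    model$branches <- br[!br$branch_id %in% drop, , drop = FALSE]
    model$cylinders <- model$cylinders[
      !model$cylinders$branch_id %in% drop, , drop = FALSE]
  }
  model
}

resolved_manifest <- function(config, extra = list()) {
  c(list(package = "rootqsm",
         version = as.character(utils::packageVersion("rootqsm"))),
    unclass(config), extra)
}

#' Reconstruct a cloud file and write model artifacts
#'
#' Reads the input cloud, runs [reconstruct_root()], and writes
#' `cylinders.csv`, `skeleton_nodes.csv`, `model.obj` and `manifest.json`
#' into `out_dir`.
#'
#' @param input path to a PLY/XYZ/LAS cloud.
#' @param out_dir output directory (created if missing).
#' @param config a [root_config()].
#' @param invert flip the vertical axis before modeling.
#' @param denoise run statistical outlier removal.
#' @return named vector of output paths, invisibly.
#' @export
cmd_reconstruct <- function(input, out_dir, config = root_config(),
                            invert = FALSE, denoise = TRUE) {
  cloud <- read_point_cloud(input)
  res <- reconstruct_root(cloud, config = config, invert = invert,
                          denoise = denoise)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cylinders = file.path(out_dir, "cylinders.csv"),
    skeleton = file.path(out_dir, "skeleton_nodes.csv"),
    obj = file.path(out_dir, "model.obj"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_model_csv(res$model, paths["cylinders"])
  utils::write.csv(res$skeleton$nodes, paths["skeleton"], row.names = FALSE)
  write_model_obj(res$model, paths["obj"])
  jsonlite::write_json(
    resolved_manifest(config, list(
      input = input, invert = invert, denoise = denoise,
      n_points = nrow(res$cloud), n_nodes = nrow(res$skeleton$nodes),
      n_cylinders = nrow(res$model$cylinders),
      n_branches = nrow(res$model$branches))),
    paths["manifest"], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Reconstruct and write the trait table
#'
#' @inheritParams cmd_reconstruct
#' @param tree_id label for the trait row.
#' @return the trait tibble, invisibly; writes `traits.csv` and
#'   `manifest.json` into `out_dir`.
#' @export
cmd_traits <- function(input, out_dir, config = root_config(),
                       invert = FALSE, denoise = TRUE, tree_id = "root") {
  cloud <- read_point_cloud(input)
  res <- reconstruct_root(cloud, config = config, invert = invert,
                          denoise = denoise)
  traits <- extract_traits(res$model, data = res$cloud,
                           min_basal_diameter_cm = config$min_basal_diameter_cm,
                           tree_id = tree_id)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(traits, file.path(out_dir, "traits.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    resolved_manifest(config, list(input = input, tree_id = tree_id)),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(traits)
}

#' Evaluate detected roots against a reference
#'
#' Detection accuracy per branching order (recall/precision/F1, plus
#' accuracy when a candidate universe gives true negatives) and, when both
#' tables carry an `rd_cm` column, regression-style diameter agreement over
#' the matched pairs. Overall detection rows are reported under both
#' aggregations: pooled confusion counts and the mean of per-order metrics.
#'
#' @param detected,reference data frames (or CSV paths) with columns
#'   `order`, `x`, `y`, `z` and optionally `rd_cm`.
#' @param tol match tolerance in meters.
#' @return a list with `detection` (per-order + overall rows) and
#'   `diameters` (a [regression_report()] row, or `NULL`).
#' @export
cmd_evaluate <- function(detected, reference, tol = 0.1) {
  if (is.character(detected)) detected <- utils::read.csv(detected)
  if (is.character(reference)) reference <- utils::read.csv(reference)
  detected <- as_tibble(detected)
  reference <- as_tibble(reference)

  orders <- sort(unique(c(detected$order, reference$order)))
  per_order <- purrr::map_dfr(orders, function(o) {
    cnt <- match_roots(detected[detected$order == o, ],
                       reference[reference$order == o, ], tol = tol)
    dplyr::bind_cols(tibble(scope = paste0("order_", o)),
                     detection_report(cnt, digits = NULL))
  })
  pooled <- detection_report(
    tibble(tp = sum(per_order$tp), fp = sum(per_order$fp),
           fn = sum(per_order$fn), tn = NA_integer_), digits = NULL)
  detection <- dplyr::bind_rows(
    per_order,
    dplyr::bind_cols(tibble(scope = "overall_pooled"), pooled),
    tibble(scope = "overall_mean", tp = NA_integer_, fp = NA_integer_,
           fn = NA_integer_, tn = NA_integer_,
           recall = mean(per_order$recall),
           precision = mean(per_order$precision),
           f1 = mean(per_order$f1),
           accuracy = NA_real_)
  )

  diameters <- NULL
  if ("rd_cm" %in% names(detected) && "rd_cm" %in% names(reference)) {
    pairs <- match_root_pairs(detected, reference, tol = tol)
    if (nrow(pairs) >= 2) {
      paired <- tibble(truth = reference$rd_cm[pairs$ref],
                       estimate = detected$rd_cm[pairs$det])
      diameters <- regression_report(paired, truth, estimate)
    }
  }
  list(detection = detection, diameters = diameters)
}

# greedy matching as in match_roots, but returning the matched index pairs
match_root_pairs <- function(detected, reference, tol) {
  out <- list()
  for (o in sort(unique(c(detected$order, reference$order)))) {
    di <- which(detected$order == o)
    ri <- which(reference$order == o)
    if (length(di) == 0 || length(ri) == 0) next
    dd <- outer(seq_along(di), seq_along(ri), function(a, b) {
      sqrt((detected$x[di[a]] - reference$x[ri[b]])^2 +
           (detected$y[di[a]] - reference$y[ri[b]])^2 +
           (detected$z[di[a]] - reference$z[ri[b]])^2)
    })
    repeat {
      if (all(!is.finite(dd)) || min(dd, na.rm = TRUE) > tol) break
      k <- arrayInd(which.min(dd), dim(dd))
      out[[length(out) + 1]] <- tibble(det = di[k[1]], ref = ri[k[2]])
      dd[k[1], ] <- Inf
      dd[, k[2]] <- Inf
    }
  }
  if (length(out) == 0) return(tibble(det = integer(0), ref = integer(0)))
  dplyr::bind_rows(out)
}

#' Write a synthetic preset fixture to disk
#'
#' @param preset `"vertical"` or `"horizontal"`.
#' @param out_dir output directory.
#' @param seed overrides the preset's fixed seed when not `NULL`.
#' @return named vector of output paths (`cloud` PLY, `branches` CSV,
#'   `traits` CSV), invisibly.
#' @export
cmd_synth <- function(preset = c("vertical", "horizontal"), out_dir,
                      seed = NULL) {
  preset <- match.arg(preset)
  spec <- vertical_and_horizontal_presets()[[preset]]
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  gen <- generate_root_system(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cloud = file.path(out_dir, paste0(preset, ".ply")),
    branches = file.path(out_dir, paste0(preset, "_branches.csv")),
    traits = file.path(out_dir, paste0(preset, "_traits.csv"))
  )
  write_point_cloud(gen$cloud, paths["cloud"])
  utils::write.csv(gen$truth$branches, paths["branches"], row.names = FALSE)
  utils::write.csv(gen$truth$traits, paths["traits"], row.names = FALSE)
  invisible(paths)
}
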