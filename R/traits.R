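#' Measure a branch's basal diameter from the point cloud
#'
#' The direct (model-free) diameter measurement: the local cloud around the
#' branch base is rotated so the branch axis is vertical, sliced into
#' `n_slabs` slabs of `slab_thickness` starting just above the attachment
#' (offset by the parent root's local radius plus 1 cm, so the parent's
#' surface stays out of the slices), each slab is projected to the plane and
#' a least-squares circle is fitted; the reported diameter is the mean of
#' the slab diameters, in cm.
#'
#' @param data the cloud the model was built from.
#' @param model a `root_model` with orders assigned.
#' @param branch_id branch to measure.
#' @param slab_thickness slab height (m), default 0.01.
#' @param n_slabs number of slabs averaged, default 3.
#' @param min_points minimum points across the slab window, default 30.
#' @return an object of class `diameter_measurement`: list with `rd_cm`,
#'   `center` (slab-plane 2-vector, m), `fit_rms` (m), `n_slices_averaged`,
#'   `branch_id`, `offset_m` (axial distance of the slab-window midpoint
#'   above the attachment) and `measure_point` (that midpoint in world
#'   coordinates) — so a reference diameter can be read off at the same
#'   cross-section.
#' @export
basal_diameter <- function(data, model, branch_id, slab_thickness = 0.01,
                           n_slabs = 3, min_points = 30) {
  data <- as_cloud(data)
  stopifnot(inherits(model, "root_model"))
  if (is.null(model$branches)) abort("basal_diameter: assign orders first.")
  br <- model$branches[model$branches$branch_id == branch_id, ]
  if (nrow(br) != 1) abort(paste0("basal_diameter: no branch ", branch_id, "."))
  cyl <- model$cylinders[model$cylinders$branch_id == branch_id, ]

  first <- cyl[1, ]
  a0 <- c(first$start_x, first$start_y, first$start_z)
  # slab orientation: blend the base chord with the first own-to-own
  # cylinder direction; the chord alone can tilt against the true branch
  # axis (turning cross-sections into ellipses and inflating the radius),
  # while the next cylinder alone can misplace the window on curved bases
  u1 <- c(first$end_x - first$start_x, first$end_y - first$start_y,
          first$end_z - first$start_z)
  u1 <- u1 / max(vnorm(u1), 1e-12)
  ax <- cyl[min(2, nrow(cyl)), ]
  u2 <- c(ax$end_x - ax$start_x, ax$end_y - ax$start_y,
          ax$end_z - ax$start_z)
  u2 <- u2 / max(vnorm(u2), 1e-12)
  u <- u1 + u2
  u <- u / max(vnorm(u), 1e-12)

  # clearance above the attachment: parent root's local radius + 1 cm
  clearance <- 0.01
  if (!is.na(br$parent_branch)) {
    pj <- model$cylinders$to_node == br$attach_node &
      model$cylinders$branch_id != branch_id
    rp <- model$cylinders$radius[pj]
    if (any(is.finite(rp))) clearance <- clearance + max(rp[is.finite(rp)])
  }

  # local cloud: members of the branch's own skeleton nodes, plus the
  # attachment-side node of the first cylinder (filtered below)
  memb <- model$skeleton$membership
  own_nodes <- unique(c(first$from_node, cyl$to_node))
  idx <- which(memb %in% own_nodes)
  if (length(idx) < 3) {
    abort(paste0("basal_diameter: branch ", branch_id,
                 " has too few nearby points (", length(idx), ")."))
  }
  m <- cloud_matrix(data)[idx, , drop = FALSE]
  q <- sweep(m, 2, a0)
  t <- as.vector(q %*% u)
  r_clean <- suppressWarnings(min(head(cyl$radius, 3), na.rm = TRUE))
  r_guess <- if (is.finite(r_clean)) r_clean else
    stats::median(sqrt(pmax(rowSums(q^2) - t^2, 0)))
  radial <- sqrt(pmax(rowSums(q^2) - t^2, 0))

  near_axis <- radial <= 1.8 * max(r_guess, 1e-3)
  # the first stretch above a junction is welded to the parent surface and
  # belongs to the parent's skeleton nodes; start slicing where this
  # branch's own surface actually begins
  t_own <- t[near_axis & t >= 0]
  if (length(t_own) == 0) {
    abort(paste0("basal_diameter: branch ", branch_id,
                 " has no measurable points above its base."))
  }
  slab_start <- max(clearance, stats::quantile(t_own, 0.02) + 0.002)
  base_n <- sum(t >= 0 & t <= slab_start + 3 * n_slabs * slab_thickness &
                  near_axis)
  if (base_n < min_points) {
    abort(paste0("basal_diameter: branch ", branch_id, " has ", base_n,
                 " points near its base (need ", min_points, ")."))
  }
  e1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * u) * u; e1 <- e1 / vnorm(e1)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])

  # scan slabs upward from the base; a slab polluted by the parent surface
  # shows up as an implausible radius or a large radial residual and is
  # skipped, until n_slabs clean cross-sections are collected
  diam <- numeric(0); rms <- numeric(0); cens <- NULL; mids <- numeric(0)
  for (s in seq_len(2 * n_slabs)) {
    lo <- slab_start + (s - 1) * slab_thickness
    in_slab <- near_axis & t >= lo & t < lo + slab_thickness
    if (sum(in_slab) < 4) next
    p2 <- cbind(q[in_slab, ] %*% e1, q[in_slab, ] %*% e2)
    fit <- tryCatch(fit_circle(p2), error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$radius < 0.5 * r_guess || fit$radius > 1.8 * r_guess) next
    if (fit$rms > max(0.25 * fit$radius, 2e-3)) next
    diam <- c(diam, 2 * fit$radius)
    rms <- c(rms, fit$rms)
    cens <- rbind(cens, fit$center)
    mids <- c(mids, lo + slab_thickness / 2)
  }
  if (length(diam) == 0) {
    abort(paste0("basal_diameter: no slab of branch ", branch_id,
                 " supported a clean circle fit."))
  }
  # a slab grazing a child junction fits an inflated blob; keep the slabs
  # consistent with the median and average those
  keep_slab <- abs(diam / stats::median(diam) - 1) <= 0.15
  diam <- diam[keep_slab]; rms <- rms[keep_slab]
  cens <- cens[keep_slab, , drop = FALSE]; mids <- mids[keep_slab]
  keep_n <- min(length(diam), n_slabs)
  diam <- diam[seq_len(keep_n)]; rms <- rms[seq_len(keep_n)]
  mids <- mids[seq_len(keep_n)]
  cen <- colSums(cens[seq_len(keep_n), , drop = FALSE])
  t_mid <- mean(mids)
  structure(list(
    rd_cm = mean(diam) * 100,
    center = cen / length(diam),
    fit_rms = mean(rms),
    n_slices_averaged = length(diam),
    branch_id = branch_id,
    offset_m = t_mid,
    measure_point = a0 + t_mid * u
  ), class = "diameter_measurement")
}

#' @export
print.diameter_measurement <- function(x, ...) {
  cat("<diameter_measurement> branch ", x$branch_id, ": RD ",
      signif(x$rd_cm, 4), " cm (", x$n_slices_averaged, " slices, rms ",
      signif(x$fit_rms, 3), " m)\n", sep = "")
  invisible(x)
}

#' Per-branch basal diameters and attachment positions
#'
#' Measures every branch with [basal_diameter()]; branches whose slab
#' measurement is infeasible (too few points) fall back to twice the first
#' fitted cylinder radius and are marked `rd_source = "model"`.
#'
#' @param model a `root_model` with orders assigned.
#' @param data the source cloud; when `NULL` all diameters come from the
#'   fitted cylinders.
#' @return a tibble: `branch_id`, `order`, `attach_x/y/z`, `rd_cm`,
#'   `rd_source`, `rd_offset_m` and the measurement cross-section position
#'   `measure_x/y/z` (NA for model-side fallbacks).
#' @export
measure_branches <- function(model, data = NULL) {
  stopifnot(inherits(model, "root_model"))
  if (is.null(model$branches)) abort("measure_branches: assign orders first.")
  br <- model$branches
  rd <- rep(NA_real_, nrow(br))
  src <- rep("model", nrow(br))
  off <- rep(NA_real_, nrow(br))
  mp <- matrix(NA_real_, nrow(br), 3)
  if (!is.null(data)) {
    for (i in seq_len(nrow(br))) {
      dm <- tryCatch(basal_diameter(data, model, br$branch_id[i]),
                     error = function(e) NULL)
      if (!is.null(dm)) {
        rd[i] <- dm$rd_cm
        src[i] <- "cloud"
        off[i] <- dm$offset_m
        mp[i, ] <- dm$measure_point
      }
    }
  }
  fallback <- !is.finite(rd)
  if (any(fallback)) {
    # a branch's first cylinder shares the junction node's mixed points and
    # overestimates; the smallest of the first three radii is the cleanest
    # model-side basal estimate
    cyl <- model$cylinders
    rd[fallback] <- vapply(br$branch_id[fallback], function(b) {
      r <- cyl$radius[cyl$branch_id == b]
      200 * min(head(r, 3), na.rm = TRUE)
    }, numeric(1))
  }
  tibble(
    branch_id = br$branch_id,
    order = br$order,
    attach_x = br$attach_x, attach_y = br$attach_y, attach_z = br$attach_z,
    rd_cm = rd,
    rd_source = src,
    rd_offset_m = off,
    measure_x = mp[, 1], measure_y = mp[, 2], measure_z = mp[, 3]
  )
}

#' Extract the phenotype table of a root model
#'
#' Totals are additive over cylinders: length is the sum of cylinder
#' lengths, volume `sum(pi r^2 L)`, surface area the lateral surface
#' `sum(2 pi r L)` (end caps are internal at joints). Root counts follow the
#' coarse-root field protocol: a branch is counted iff its measured basal
#' diameter exceeds `min_basal_diameter_cm` (default 0.5 cm), and `n_roots`
#' sums the taproot and first- and second-order laterals only.
#' `mean_basal_diameter_cm` averages the counted branches' diameters.
#'
#' @param model a `root_model` with orders assigned.
#' @param data optional source cloud for direct slab-circle diameter
#'   measurement (see [measure_branches()]).
#' @param min_basal_diameter_cm coarse-root threshold in cm.
#' @param tree_id label for the output row.
#' @return a one-row tibble (the trait table) with per-order count columns
#'   `n_order0`, `n_order1`, ...
#' @export
extract_traits <- function(model, data = NULL, min_basal_diameter_cm = 0.5,
                           tree_id = "root") {
  stopifnot(inherits(model, "root_model"))
  if (is.null(model$branches)) {
    abort("extract_traits: branching orders have not been assigned.")
  }
  cyl <- model$cylinders
  meas <- measure_branches(model, data)
  counted <- meas[meas$rd_cm > min_basal_diameter_cm, ]
  in_count <- counted[counted$order <= 2, ]
  max_ord <- max(meas$order)
  count_cols <- setNames(
    lapply(0:max_ord, function(o) sum(counted$order == o)),
    paste0("n_order", 0:max_ord)
  )
  dplyr::bind_cols(
    tibble(
      tree_id = tree_id,
      n_roots = nrow(in_count),
      mean_basal_diameter_cm = if (nrow(in_count)) mean(in_count$rd_cm) else NA_real_,
      root_length_m = sum(cyl$length),
      root_volume_m3 = sum(pi * cyl$radius^2 * cyl$length),
      root_surface_area_m2 = sum(2 * pi * cyl$radius * cyl$length)
    ),
    as_tibble(count_cols)
  )
}

#' Sweep the thinning parameter (CP) through the full pipeline
#'
#' Runs downsample -> skeleton -> cylinder model -> traits once per CP value
#' and collects one trait row per CP plus the post-thinning point count.
#' A failing stage is recorded in the `error` column without aborting the
#' remaining CP values.
#'
#' @param data an inverted, denoised cloud.
#' @param cps CP values (voxel edge, m), each >= 0.
#' @param config pipeline configuration from [root_config()].
#' @param tree_id label carried into each row.
#' @return a tibble with columns `cp`, `n_points`, the trait columns and
#'   `error`.
#' @export
cp_sweep <- function(data, cps, config = root_config(), tree_id = "root") {
  data <- as_cloud(data)
  if (length(cps) == 0) abort("cp_sweep: `cps` must be non-empty.")
  if (any(cps < 0)) abort("cp_sweep: CP values must be >= 0.")
  purrr::map_dfr(cps, function(cp) {
    cfg <- config
    cfg$cp <- cp
    out <- tryCatch({
      res <- reconstruct_root(data, config = cfg, denoise = FALSE)
      tr <- extract_traits(res$model, data = res$cloud,
                           min_basal_diameter_cm = config$min_basal_diameter_cm,
                           tree_id = tree_id)
      dplyr::bind_cols(tibble(cp = cp, n_points = nrow(res$cloud)), tr,
                       tibble(error = NA_character_))
    }, error = function(e) {
      tibble(cp = cp, n_points = NA_integer_, tree_id = tree_id,
             error = conditionMessage(e))
    })
    out
  })
}

#' Plot a CP sweep
#'
#' @param object a tibble from [cp_sweep()].
#' @param ... unused.
#' @return a ggplot faceted by trait.
#' @export
plot_cp_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "cp", "mean_basal_diameter_cm", "root_length_m",
                  "root_volume_m3", "root_surface_area_m2"),
    -"cp", names_to = "trait", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cp, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "CP (voxel edge, m)", y = NULL,
                  title = "Trait variation with point-cloud thinning") +
    ggplot2::theme_minimal()
}
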