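#' Specification for a synthetic root system
#'
#' Parameter set for the procedural generator. Defaults describe an
#' excavated, mature deep-rooted ornamental tree scanned at close range with
#' a terrestrial laser scanner: a taproot reaching ~1.8 m with linearly
#' tapering radius, first- and second-order laterals inserted at jittered
#' stratified heights and azimuths, surface sampling around 2e4 points/m2
#' (sub-centimeter spacing) and millimeter Gaussian range noise.
#'
#' @param taproot_length taproot length (m).
#' @param taproot_basal_radius taproot radius at the collar (m).
#' @param taper_rate linear radius decay per meter of arc length; radius is
#'   floored at 20 percent of a branch's basal radius.
#' @param n_first_order number of first-order laterals.
#' @param n_second_order_per_first second-order laterals per first-order.
#' @param branch_angle_deg mean insertion angle from the parent axis.
#' @param lateral_length_ratio mean first-order lateral length as a fraction
#'   of the taproot length; the main lever separating vertical habits
#'   (laterals shorter than the taproot) from horizontal habits (lateral
#'   spread exceeding rooting depth). Second-order laterals are half their
#'   parent's length on average.
#' @param child_radius_ratio child basal radius as a fraction of the parent
#'   radius at the attachment.
#' @param point_density surface sampling density (points per m2).
#' @param noise_sigma radial Gaussian noise standard deviation (m).
#' @param occlusion_fraction fraction of each cylinder's circumference
#'   removed as one contiguous angular sector (scanner shadow), in `[0, 1)`.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return an object of class `root_synth_spec`.
#' @export
root_synth_spec <- function(taproot_length = 1.8,
                            taproot_basal_radius = 0.05,
                            taper_rate = 0.35,
                            n_first_order = 5,
                            n_second_order_per_first = 2,
                            branch_angle_deg = 55,
                            lateral_length_ratio = 0.45,
                            child_radius_ratio = 0.55,
                            point_density = 20000,
                            noise_sigma = 0.001,
                            occlusion_fraction = 0,
                            seed = 1) {
  spec <- list(
    taproot_length = taproot_length,
    taproot_basal_radius = taproot_basal_radius,
    taper_rate = taper_rate,
    n_first_order = as.integer(n_first_order),
    n_second_order_per_first = as.integer(n_second_order_per_first),
    branch_angle_deg = branch_angle_deg,
    lateral_length_ratio = lateral_length_ratio,
    child_radius_ratio = child_radius_ratio,
    point_density = point_density,
    noise_sigma = noise_sigma,
    occlusion_fraction = occlusion_fraction,
    seed = as.integer(seed)
  )
  stopifnot(
    taproot_length > 0, taproot_basal_radius > 0, taper_rate >= 0,
    spec$n_first_order >= 0, spec$n_second_order_per_first >= 0,
    lateral_length_ratio > 0, point_density > 0, noise_sigma >= 0,
    occlusion_fraction >= 0, occlusion_fraction < 1,
    child_radius_ratio > 0, child_radius_ratio <= 1
  )
  structure(spec, class = "root_synth_spec")
}

#' @export
print.root_synth_spec <- function(x, ...) {
  cat("<root_synth_spec> taproot ", x$taproot_length, " m x r",
      x$taproot_basal_radius, " m; ", x$n_first_order, " first-order x ",
      x$n_second_order_per_first, " second-order laterals; density ",
      x$point_density, "/m2; noise ", x$noise_sigma * 1000,
      " mm; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

SEG_LEN <- 0.1 # cylinder discretization step (m) of the true structure

# Jittered unit direction: previous direction plus isotropic perturbation.
# The vertical component is floored at a small positive value: in the
# inverted (collar-down) frame root growth never turns back above the
# soil surface.
jitter_dir <- function(u, sd) {
  v <- u + stats::rnorm(3, 0, sd)
  v <- v / vnorm(v)
  if (v[3] < 0.02) {
    v[3] <- 0.02
    v <- v / vnorm(v)
  }
  v
}

# Direction at `angle` (rad) from parent direction u, azimuth phi.
insertion_dir <- function(u, angle, phi) {
  e1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * u) * u; e1 <- e1 / vnorm(e1)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  cos(angle) * u + sin(angle) * (cos(phi) * e1 + sin(phi) * e2)
}

# Build one branch as a chain of constant-radius segments following a
# linearly tapering radius profile. Returns segment table plus a sampler of
# (position, direction, radius) at arc length s.
grow_branch <- function(start, dir0, length, r0, taper_rate, branch_id,
                        order, parent_branch) {
  n_seg <- max(2L, as.integer(ceiling(length / SEG_LEN)))
  slen <- length / n_seg
  pos <- matrix(NA_real_, n_seg + 1, 3)
  pos[1, ] <- start
  dirs <- matrix(NA_real_, n_seg, 3)
  u <- dir0
  if (u[3] < 0.02) {
    u[3] <- 0.02
    u <- u / vnorm(u)
  }
  for (i in seq_len(n_seg)) {
    dirs[i, ] <- u
    pos[i + 1, ] <- pos[i, ] + slen * u
    u <- jitter_dir(u, 0.04)
  }
  s_mid <- (seq_len(n_seg) - 0.5) * slen
  radius <- r0 * pmax(1 - taper_rate * s_mid, 0.2)
  tibble(
    branch_id = branch_id, order = order, parent_branch = parent_branch,
    seg = seq_len(n_seg),
    start_x = pos[-(n_seg + 1), 1], start_y = pos[-(n_seg + 1), 2],
    start_z = pos[-(n_seg + 1), 3],
    end_x = pos[-1, 1], end_y = pos[-1, 2], end_z = pos[-1, 3],
    radius = radius, length = slen, s_start = (seq_len(n_seg) - 1) * slen
  )
}

# interpolate (position, direction, radius) at arc length s of a branch
branch_at <- function(segs, s) {
  i <- max(1L, min(nrow(segs), findInterval(s, segs$s_start)))
  u <- c(segs$end_x[i] - segs$start_x[i], segs$end_y[i] - segs$start_y[i],
         segs$end_z[i] - segs$start_z[i])
  u <- u / vnorm(u)
  f <- (s - segs$s_start[i])
  list(
    pos = c(segs$start_x[i], segs$start_y[i], segs$start_z[i]) + f * u,
    dir = u,
    radius = segs$radius[i]
  )
}

# stratified jittered positions: n values spread over [lo, hi] of total
strat_positions <- function(n, lo, hi, total) {
  if (n == 0) return(numeric(0))
  w <- (hi - lo) / n
  (lo + (seq_len(n) - 1) * w + stats::runif(n, 0.15, 0.85) * w) * total
}

#' Generate a synthetic root-system point cloud with ground truth
#'
#' Builds the true cylinder tree (tapered taproot plus first- and
#' second-order laterals at jittered stratified insertion points), samples
#' each cylinder's lateral surface with a Poisson point process at the
#' requested density using per-cylinder seeded substreams, perturbs points
#' radially with Gaussian noise, and optionally removes one contiguous
#' angular sector per cylinder (scanner shadow). The cloud is produced in
#' modeling orientation: collar at the origin, growth direction +z.
#'
#' @param spec a [root_synth_spec()].
#' @return a list with `cloud` (tibble of points), `truth` (list with
#'   `cylinders`, `branches`, `traits` — the trait table computed in closed
#'   form from the true cylinders), and `spec`.
#' @export
generate_root_system <- function(spec = root_synth_spec()) {
  stopifnot(inherits(spec, "root_synth_spec"))
  truth <- withr::with_seed(spec$seed, build_structure(spec))
  cyl <- truth$cylinders
  pts <- vector("list", nrow(cyl))
  for (i in seq_len(nrow(cyl))) {
    pts[[i]] <- withr::with_seed(
      derive_seed(spec$seed, i),
      sample_cylinder(cyl[i, ], spec)
    )
  }
  mat <- do.call(rbind, pts)
  colnames(mat) <- c("x", "y", "z")
  cloud <- as_tibble(mat)
  list(cloud = cloud, truth = truth, spec = spec)
}

build_structure <- function(spec) {
  angle0 <- spec$branch_angle_deg * pi / 180
  segs_list <- list()
  branch_rows <- list()
  next_id <- 0L

  add_branch <- function(start, dir0, length, r0, order, parent_branch,
                         attach) {
    next_id <<- next_id + 1L
    id <- next_id
    segs <- grow_branch(start, dir0, length, r0, spec$taper_rate, id, order,
                        parent_branch)
    segs_list[[id]] <<- segs
    branch_rows[[id]] <<- tibble(
      branch_id = id, order = order, parent_branch = parent_branch,
      x = attach[1], y = attach[2], z = attach[3],
      basal_radius = r0, length = length
    )
    id
  }

  tap <- add_branch(c(0, 0, 0), c(0, 0, 1), spec$taproot_length,
                    spec$taproot_basal_radius, 0L, NA_integer_, c(0, 0, 0))

  s1 <- strat_positions(spec$n_first_order, 0.15, 0.85, spec$taproot_length)
  phi1 <- 2 * pi * (seq_len(spec$n_first_order) - 1) / max(spec$n_first_order, 1) +
    stats::rnorm(spec$n_first_order, 0, 0.25)
  for (j in seq_len(spec$n_first_order)) {
    at <- branch_at(segs_list[[tap]], s1[j])
    ang <- angle0 + stats::rnorm(1, 0, 0.12)
    dir <- insertion_dir(at$dir, ang, phi1[j])
    len <- spec$taproot_length * spec$lateral_length_ratio *
      stats::runif(1, 0.85, 1.15)
    r0 <- spec$child_radius_ratio * at$radius
    b1 <- add_branch(at$pos, dir, len, r0, 1L, tap, at$pos)

    s2 <- strat_positions(spec$n_second_order_per_first, 0.25, 0.8, len)
    phi2 <- stats::runif(spec$n_second_order_per_first, 0, 2 * pi)
    for (k in seq_len(spec$n_second_order_per_first)) {
      at2 <- branch_at(segs_list[[b1]], s2[k])
      ang2 <- angle0 + stats::rnorm(1, 0, 0.12)
      dir2 <- insertion_dir(at2$dir, ang2, phi2[k])
      len2 <- len * 0.5 * stats::runif(1, 0.85, 1.15)
      r02 <- spec$child_radius_ratio * at2$radius
      add_branch(at2$pos, dir2, len2, r02, 2L, b1, at2$pos)
    }
  }

  cylinders <- dplyr::bind_rows(segs_list)
  branches <- dplyr::bind_rows(branch_rows)
  list(
    cylinders = cylinders,
    branches = branches,
    traits = truth_traits(cylinders, branches)
  )
}

# Closed-form trait table from the true cylinders (piecewise-constant radius
# profile, so sums are exact).
truth_traits <- function(cylinders, branches, min_basal_diameter_cm = 0.5,
                         tree_id = "truth") {
  d_cm <- 200 * branches$basal_radius
  counted <- branches[d_cm > min_basal_diameter_cm, ]
  in_count <- counted[counted$order <= 2, ]
  max_ord <- max(branches$order)
  count_cols <- setNames(
    lapply(0:max_ord, function(o) sum(counted$order == o)),
    paste0("n_order", 0:max_ord)
  )
  dplyr::bind_cols(
    tibble(
      tree_id = tree_id,
      n_roots = nrow(in_count),
      mean_basal_diameter_cm = mean(200 * in_count$basal_radius),
      root_length_m = sum(cylinders$length),
      root_volume_m3 = sum(pi * cylinders$radius^2 * cylinders$length),
      root_surface_area_m2 = sum(2 * pi * cylinders$radius * cylinders$length)
    ),
    as_tibble(count_cols)
  )
}

# Poisson surface sampling of one cylinder with radial noise and an
# occluded angular sector.
sample_cylinder <- function(cyl, spec) {
  u <- c(cyl$end_x - cyl$start_x, cyl$end_y - cyl$start_y,
         cyl$end_z - cyl$start_z)
  L <- vnorm(u)
  u <- u / L
  lambda <- spec$point_density * 2 * pi * cyl$radius * L
  n <- stats::rpois(1, lambda)
  theta0 <- stats::runif(1, 0, 2 * pi) # shadow sector start (always drawn)
  if (n == 0) return(matrix(numeric(0), 0, 3))
  t <- stats::runif(n, 0, L)
  th <- stats::runif(n, 0, 2 * pi)
  rr <- cyl$radius + stats::rnorm(n, 0, spec$noise_sigma)
  if (spec$occlusion_fraction > 0) {
    rel <- (th - theta0) %% (2 * pi)
    keep <- rel >= 2 * pi * spec$occlusion_fraction
    t <- t[keep]; th <- th[keep]; rr <- rr[keep]
  }
  e1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * u) * u; e1 <- e1 / vnorm(e1)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  s <- c(cyl$start_x, cyl$start_y, cyl$start_z)
  cbind(
    s[1] + t * u[1] + rr * (cos(th) * e1[1] + sin(th) * e2[1]),
    s[2] + t * u[2] + rr * (cos(th) * e1[2] + sin(th) * e2[2]),
    s[3] + t * u[3] + rr * (cos(th) * e1[3] + sin(th) * e2[3])
  )
}

#' True diameter of a synthetic branch at a given point
#'
#' Looks up the ground-truth cylinder of `branch_id` nearest to `point` and
#' returns its diameter in cm. Used to compare a measured diameter against
#' the truth at the same cross-section, the way caliper and cloud
#' measurements are co-located on a real root.
#'
#' @param truth the `truth` component of [generate_root_system()] output.
#' @param branch_id ground-truth branch id.
#' @param point numeric 3-vector (m).
#' @return diameter in cm.
#' @export
truth_diameter_at <- function(truth, branch_id, point) {
  cy <- truth$cylinders[truth$cylinders$branch_id == branch_id, ]
  if (nrow(cy) == 0) abort("truth_diameter_at: unknown branch id.")
  s <- as.matrix(cy[, c("start_x", "start_y", "start_z")])
  e <- as.matrix(cy[, c("end_x", "end_y", "end_z")])
  d2 <- vapply(seq_len(nrow(cy)), function(i) {
    u <- e[i, ] - s[i, ]
    L <- vnorm(u)
    u <- u / L
    t <- min(max(sum((point - s[i, ]) * u), 0), L)
    sum((point - (s[i, ] + t * u))^2)
  }, numeric(1))
  200 * cy$radius[which.min(d2)]
}

#' Vertical and horizontal root-system presets
#'
#' Two fixed generator configurations mirroring the two excavated root
#' habits seen in the field: a "vertical" system with a long, deep taproot
#' and steeply descending laterals, and a "horizontal" system with a short
#' taproot and wide, shallow laterals. Seeds are fixed so both serve as
#' reproducible fixtures.
#'
#' @return a named list of two [root_synth_spec()] objects,
#'   `vertical` and `horizontal`.
#' @export
vertical_and_horizontal_presets <- function() {
  list(
    vertical = root_synth_spec(
      taproot_length = 1.8, taproot_basal_radius = 0.05,
      branch_angle_deg = 40, n_first_order = 5,
      n_second_order_per_first = 2, seed = 101
    ),
    horizontal = root_synth_spec(
      taproot_length = 0.9, taproot_basal_radius = 0.055,
      branch_angle_deg = 72, lateral_length_ratio = 1.3,
      n_first_order = 6, n_second_order_per_first = 2, seed = 202
    )
  )
}
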