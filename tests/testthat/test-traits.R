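test_that("single-cylinder traits match the closed forms", {
  model <- single_cylinder_model(radius = 0.05, length = 1.0)
  tr <- extract_traits(model)
  expect_equal(tr$root_length_m, 1.0)
  expect_equal(tr$root_volume_m3, pi * 0.05^2, tolerance = 1e-12)
  expect_equal(tr$root_surface_area_m2, 2 * pi * 0.05, tolerance = 1e-12)
  expect_equal(tr$n_roots, 1)
  expect_equal(tr$mean_basal_diameter_cm, 10)
})

test_that("totals are additive over branches", {
  model <- single_cylinder_model()
  cyl2 <- model$cylinders
  cyl2$cyl_id <- 2L; cyl2$branch_id <- 2L; cyl2$order <- 1L
  cyl2$radius <- 0.02; cyl2$length <- 0.5; cyl2$end_z <- 0.5
  cyl2$from_node <- 2L; cyl2$to_node <- 3L
  br2 <- model$branches
  br2$branch_id <- 2L; br2$order <- 1L; br2$parent_branch <- 1L
  br2$basal_radius <- 0.02; br2$length <- 0.5
  model$cylinders <- rbind(model$cylinders, cyl2)
  model$branches <- rbind(model$branches, br2)
  tr <- extract_traits(model)
  expect_equal(tr$root_length_m, 1.5, tolerance = 1e-9)
  expect_equal(tr$root_volume_m3, pi * (0.05^2 * 1 + 0.02^2 * 0.5),
               tolerance = 1e-9)
  expect_equal(tr$root_surface_area_m2, 2 * pi * (0.05 * 1 + 0.02 * 0.5),
               tolerance = 1e-9)
})

test_that("the coarse-root threshold filters counts monotonically", {
  model <- single_cylinder_model()
  # two laterals with basal diameters 0.4 cm and 0.6 cm
  add <- function(m, id, r) {
    cyl <- m$cylinders[1, ]
    cyl$cyl_id <- id; cyl$branch_id <- id; cyl$order <- 1L
    cyl$radius <- r; cyl$length <- 0.3
    cyl$from_node <- 2L; cyl$to_node <- 2L + id
    br <- m$branches[1, ]
    br$branch_id <- id; br$order <- 1L; br$parent_branch <- 1L
    br$basal_radius <- r
    m$cylinders <- rbind(m$cylinders, cyl)
    m$branches <- rbind(m$branches, br)
    m
  }
  model <- add(model, 2L, 0.002)
  model <- add(model, 3L, 0.003)
  at <- function(thr) extract_traits(model, min_basal_diameter_cm = thr)
  expect_equal(at(0.5)$n_order1, 1)   # only the 0.6 cm lateral
  expect_equal(at(0)$n_order1, 2)
  expect_equal(at(1)$n_order1, 0)
  # raising the threshold never increases any count
  thr <- c(0, 0.25, 0.5, 0.75, 2, 12)
  counts <- vapply(thr, function(t0) at(t0)$n_roots, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(extract_traits(model_from_skeleton_missing <- local({
    m <- model; m$branches <- NULL; m
  })), "orders")
})

test_that("basal diameter of a clean taproot is read off the cloud", {
  spec <- root_synth_spec(taproot_length = 0.6, taproot_basal_radius = 0.025,
                          n_first_order = 0, n_second_order_per_first = 0,
                          noise_sigma = 0, seed = 31)
  gen <- generate_root_system(spec)
  res <- reconstruct_root(gen$cloud, root_config(hs = 0.05, cp = 0.003),
                          denoise = FALSE)
  dm <- basal_diameter(res$cloud, res$model, 1)
  expect_s3_class(dm, "diameter_measurement")
  # true diameter 5 cm at the base, linear taper along the measurement offset
  truth_at <- truth_diameter_at(gen$truth, 1, dm$measure_point)
  expect_lt(abs(dm$rd_cm - truth_at) / truth_at, 0.02)
  expect_gte(dm$n_slices_averaged, 1)
})

test_that("basal diameter demands enough points near the base", {
  model <- single_cylinder_model()
  sparse <- tibble::tibble(x = rep(0.05, 10), y = 0,
                           z = seq(0.05, 0.95, length.out = 10))
  expect_error(basal_diameter(sparse, model, 1), "points")
  expect_error(basal_diameter(sparse, model, 99), "no branch")
})

test_that("cp_sweep returns one row per CP with cp = 0 equal to no thinning", {
  spec <- root_synth_spec(taproot_length = 0.5, taproot_basal_radius = 0.02,
                          n_first_order = 1, n_second_order_per_first = 0,
                          point_density = 15000, noise_sigma = 0, seed = 33)
  gen <- generate_root_system(spec)
  cfg <- root_config(hs = 0.05, cp = 0)
  sw <- cp_sweep(gen$cloud, cps = c(0, 0.004), config = cfg, tree_id = "t1")
  expect_equal(nrow(sw), 2)
  expect_true(all(sw$tree_id == "t1"))
  expect_true(all(is.na(sw$error)))
  # cp = 0 row equals a direct run without thinning
  direct <- reconstruct_root(gen$cloud, cfg, denoise = FALSE)
  tr <- extract_traits(direct$model, data = direct$cloud, tree_id = "t1")
  expect_equal(sw$root_length_m[1], tr$root_length_m, tolerance = 1e-9)
  # voxel grids share a fixed origin, so point counts nest monotonically
  expect_true(all(diff(sw$n_points) <= 0))
})
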