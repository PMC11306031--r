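small_spec <- function(seed = 41, ...) {
  root_synth_spec(taproot_length = 0.6, taproot_basal_radius = 0.03,
                  n_first_order = 2, n_second_order_per_first = 1,
                  point_density = 8000, seed = seed, ...)
}

test_that("identical seeds generate bit-identical clouds and truth", {
  a <- generate_root_system(small_spec())
  b <- generate_root_system(small_spec())
  expect_identical(a$cloud, b$cloud)
  expect_identical(a$truth, b$truth)
  c <- generate_root_system(small_spec(seed = 42))
  expect_false(identical(a$cloud, c$cloud))
})

test_that("per-order branch counts follow the spec by construction", {
  spec <- root_synth_spec(n_first_order = 5, n_second_order_per_first = 2,
                          point_density = 1000, seed = 43)
  gen <- generate_root_system(spec)
  tt <- gen$truth$traits
  expect_equal(c(tt$n_order0, tt$n_order1, tt$n_order2), c(1, 5, 10))
  expect_equal(tt$n_roots, 16)
  # ground-truth traits are closed-form sums over the true cylinders
  cy <- gen$truth$cylinders
  expect_equal(tt$root_volume_m3, sum(pi * cy$radius^2 * cy$length),
               tolerance = 1e-12)
  expect_equal(tt$root_length_m, sum(cy$length), tolerance = 1e-12)
})

test_that("realized point counts concentrate at the Poisson mean", {
  inside <- 0
  for (s in 1:12) {
    spec <- small_spec(seed = 100 + s)
    gen <- generate_root_system(spec)
    lambda <- spec$point_density *
      sum(2 * pi * gen$truth$cylinders$radius * gen$truth$cylinders$length)
    expect_lt(abs(nrow(gen$cloud) - lambda), 4 * sqrt(lambda))
    inside <- inside + (abs(nrow(gen$cloud) - lambda) < 2 * sqrt(lambda))
  }
  expect_gte(inside, 9) # ~95% of draws inside 2 sigma
})

test_that("sampled points stay within 6 sigma of their cylinder surface", {
  spec <- small_spec(noise_sigma = 0.002, seed = 44)
  gen <- generate_root_system(spec)
  cy <- gen$truth$cylinders
  pts <- as.matrix(gen$cloud[sample.int(nrow(gen$cloud), 300), ])
  surf_dev <- apply(pts, 1, function(p) {
    min(vapply(seq_len(nrow(cy)), function(i) {
      s <- c(cy$start_x[i], cy$start_y[i], cy$start_z[i])
      e <- c(cy$end_x[i], cy$end_y[i], cy$end_z[i])
      u <- e - s; L <- sqrt(sum(u^2)); u <- u / L
      t <- min(max(sum((p - s) * u), 0), L)
      abs(sqrt(sum((p - (s + t * u))^2)) - cy$radius[i])
    }, numeric(1)))
  })
  expect_lt(max(surf_dev), 6 * spec$noise_sigma + 1e-9)
})

test_that("occlusion removes roughly the shadowed fraction of points", {
  full <- generate_root_system(small_spec(seed = 45))
  occ <- generate_root_system(small_spec(seed = 45,
                                         occlusion_fraction = 0.3))
  ratio <- nrow(occ$cloud) / nrow(full$cloud)
  expect_lt(abs(ratio - 0.7), 0.05)
})

test_that("taper never drops below 20% of the basal radius", {
  gen <- generate_root_system(root_synth_spec(taper_rate = 2,
                                              point_density = 500, seed = 46))
  cy <- gen$truth$cylinders
  for (b in unique(cy$branch_id)) {
    r <- cy$radius[cy$branch_id == b]
    expect_gte(min(r) + 1e-12, 0.2 * max(r))
  }
})

test_that("the two habit presets differ as documented", {
  ps <- vertical_and_horizontal_presets()
  expect_named(ps, c("vertical", "horizontal"))
  zext <- vapply(ps, function(spec) {
    spec$point_density <- 500
    gen <- generate_root_system(spec)
    max(gen$truth$cylinders$end_z)
  }, numeric(1))
  expect_gt(zext["vertical"], zext["horizontal"])
  # area x density puts both presets above 1e4 points
  for (spec in ps) {
    gen <- generate_root_system(local({ spec$point_density <- 500; spec }))
    area <- sum(2 * pi * gen$truth$cylinders$radius *
                  gen$truth$cylinders$length)
    expect_gt(area * spec$point_density, 1e4)
  }
})

test_that("invalid generator parameters are rejected", {
  expect_error(root_synth_spec(taproot_length = -1))
  expect_error(root_synth_spec(occlusion_fraction = 1))
  expect_error(root_synth_spec(child_radius_ratio = 0))
})
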