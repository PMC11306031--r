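test_that("noiseless cylinder is recovered to machine-level accuracy", {
  cloud <- cylinder_cloud(200, radius = 0.05, length = 0.4, seed = 1,
                          regular_t = TRUE)
  fit <- fit_cylinder(cloud, init_axis = list(point = c(0.01, -0.01, 0),
                                              direction = c(0.05, 0, 1)))
  expect_equal(fit$radius, 0.05, tolerance = 1e-6)
  expect_equal(abs(sum(fit$axis * c(0, 0, 1))), 1, tolerance = 1e-6)
  expect_equal(sqrt(sum((fit$end - fit$start)^2)), 0.4, tolerance = 1e-3)
  expect_lt(fit$rmse_fit, 1e-9)
})

test_that("mean recovered radius stays within 5% under mm noise", {
  radii <- vapply(1:10, function(s) {
    cloud <- cylinder_cloud(300, radius = 0.05, length = 0.4,
                            sigma = 0.001, seed = s)
    fit_cylinder(cloud, init_axis = list(point = c(0, 0, 0),
                                         direction = c(0, 0, 1)))$radius
  }, numeric(1))
  expect_lt(abs(mean(radii) / 0.05 - 1), 0.05)
})

test_that("degenerate inputs are rejected", {
  line <- tibble::tibble(x = seq(0, 1, length.out = 6), y = 0, z = 0)
  expect_error(fit_cylinder(line, list(point = c(0, 0, 0),
                                       direction = c(1, 0, 0))))
  expect_error(fit_cylinder(cylinder_cloud(5),
                            list(point = c(0, 0, 0), direction = c(0, 0, 1))),
               "at least 7")
  expect_error(fit_cylinder(cylinder_cloud(50),
                            list(point = c(0, 0, 0), direction = c(0, 0, 0))),
               "direction")
})

test_that("NLLS radius agrees with brute-force grid search", {
  cloud <- cylinder_cloud(300, radius = 0.04, length = 0.4, seed = 9)
  fit <- fit_cylinder(cloud, init_axis = list(point = c(0, 0, 0),
                                              direction = c(0, 0, 1)))
  m <- as.matrix(cloud)
  tilt <- seq(-5, 5, by = 1) * pi / 180
  radii <- seq(0.8, 1.2, by = 0.01) * 0.04
  best <- c(Inf, NA)
  for (tx in tilt) for (ty in tilt) {
    u <- c(sin(tx), sin(ty), sqrt(max(1 - sin(tx)^2 - sin(ty)^2, 0)))
    tproj <- m %*% u
    d <- sqrt(pmax(rowSums(m^2) - tproj^2, 0))
    for (r in radii) {
      sse <- sum((d - r)^2)
      if (sse < best[1]) best <- c(sse, r)
    }
  }
  expect_lt(abs(fit$radius - best[2]), 0.01 * 0.04 + 1e-9)
})

test_that("tidy and glance expose the fit as one-row tibbles", {
  fit <- fit_cylinder(cylinder_cloud(100),
                      init_axis = list(point = c(0, 0, 0),
                                       direction = c(0, 0, 1)))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(glance(fit), c("n_points", "rmse_fit", "iterations",
                              "converged"))
})
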