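test_that("statistical outlier removal drops isolated points only", {
  # perfectly regular ring: every point's neighbour statistic is identical
  th <- 2 * pi * (0:999) / 1000
  dense <- data.frame(x = 0.05 * cos(th), y = 0.05 * sin(th), z = 0)
  kept <- remove_outliers(dense, k = 8, std_ratio = 2)
  expect_equal(nrow(kept), nrow(dense))
  # one far point: removed; second pass removes nothing more
  with_far <- rbind(dense, c(1, 1, 1))
  kept <- remove_outliers(with_far, k = 8, std_ratio = 2)
  expect_equal(nrow(kept), nrow(dense))
  expect_false(any(kept$x == 1 & kept$y == 1 & kept$z == 1))
  expect_equal(nrow(remove_outliers(kept, k = 8, std_ratio = 2)), nrow(kept))
  expect_error(remove_outliers(dense[1:5, ], k = 8), "more than")
})

test_that("voxel thinning keeps one original point per occupied voxel", {
  lattice <- expand.grid(x = seq(0, 0.009, 0.001),
                         y = seq(0, 0.009, 0.001),
                         z = seq(0, 0.009, 0.001))
  thin <- downsample_cp(lattice, cp = 0.002)
  expect_equal(nrow(thin), 125)
  # selection, not averaging: every output point is an input point
  key_in <- paste(lattice$x, lattice$y, lattice$z)
  expect_true(all(paste(thin$x, thin$y, thin$z) %in% key_in))
  # one point per voxel
  vox <- paste(floor(thin$x / 0.002), floor(thin$y / 0.002),
               floor(thin$z / 0.002))
  expect_false(any(duplicated(vox)))
  # cp = 0 is the identity, and |output| <= |input| always
  expect_identical(downsample_cp(lattice, cp = 0), tibble::as_tibble(lattice))
  for (cp in c(0.0005, 0.003, 0.01)) {
    expect_lte(nrow(downsample_cp(lattice, cp)), nrow(lattice))
  }
  expect_error(downsample_cp(lattice, cp = -1), "cp")
})
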