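test_that("ASCII PLY reads vertices in file order", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c(
    "ply", "format ascii 1.0", "element vertex 3",
    "property float x", "property float y", "property float z",
    "end_header",
    "0 0 0", "1 0 0", "0 1 0"
  ), path)
  pc <- read_point_cloud(path)
  expect_equal(nrow(pc), 3)
  expect_equal(pc$x, c(0, 1, 0))
  expect_equal(pc$y, c(0, 0, 1))
})

test_that("single-line XYZ parses", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines("1.5 2.5 3.5", path)
  pc <- read_point_cloud(path)
  expect_equal(unlist(pc[1, c("x", "y", "z")], use.names = FALSE),
               c(1.5, 2.5, 3.5))
})

test_that("write/read round-trips hold for every format", {
  cloud <- cylinder_cloud(500, sigma = 0.001, seed = 7)
  for (fmt in c("ply", "xyz", "las")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_point_cloud(cloud, path)
    back <- read_point_cloud(path)
    tol <- if (fmt == "las") 5.1e-5 else 1e-6 # LAS quantizes at 0.1 mm
    expect_lt(max(abs(as.matrix(back[, 1:3]) - as.matrix(cloud[, 1:3]))),
              tol)
  }
  # binary PLY too
  path <- withr::local_tempfile(fileext = ".ply")
  write_point_cloud(cloud, path, binary = TRUE)
  back <- read_point_cloud(path)
  expect_lt(max(abs(as.matrix(back[, 1:3]) - as.matrix(cloud[, 1:3]))),
            1e-6)
})

test_that("PLY writer emits a conforming vertex header", {
  path <- withr::local_tempfile(fileext = ".ply")
  write_point_cloud(tibble::tibble(x = 1:3, y = 0, z = 0), path)
  hdr <- readLines(path, n = 3)
  expect_equal(hdr[3], "element vertex 3")
})

test_that("empty clouds are rejected on write and read", {
  empty <- tibble::tibble(x = numeric(), y = numeric(), z = numeric())
  expect_error(write_point_cloud(empty, tempfile(fileext = ".xyz")),
               "empty")
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(character(0), path)
  expect_error(read_point_cloud(path))
})

test_that("axis inversion is an involution that mirrors z in its range", {
  cloud <- cylinder_cloud(300, seed = 2)
  inv <- invert_axis(cloud)
  expect_equal(invert_axis(inv), cloud)
  expect_equal(range(inv$z), range(cloud$z))
  expect_equal(mean(inv$z), min(cloud$z) + max(cloud$z) - mean(cloud$z))
  # the top point becomes the bottom point
  expect_equal(which.min(inv$z), which.max(cloud$z))
  # rigid: pairwise distances preserved
  idx <- 1:20
  expect_equal(c(dist(as.matrix(inv[idx, 1:3]))),
               c(dist(as.matrix(cloud[idx, 1:3]))), tolerance = 1e-12)
})

test_that("crop_box keeps exactly the closed-box points", {
  grid <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  cropped <- crop_box(grid, c(0, 0, 0), c(1, 1, 1))
  expect_equal(nrow(cropped), 8)
  expect_true(all(cropped$x >= 0 & cropped$x <= 1))
  # identity when the box covers everything
  expect_equal(nrow(crop_box(grid, c(-2, -2, -2), c(2, 2, 2))), 27)
  # subset property: every output row exists in the input
  expect_true(all(apply(cropped, 1, function(p)
    any(grid$x == p[1] & grid$y == p[2] & grid$z == p[3]))))
  expect_error(crop_box(grid, c(5, 5, 5), c(6, 6, 6)), "0 of")
  expect_error(crop_box(grid, c(1, 0, 0), c(0, 1, 1)), "lo")
})
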