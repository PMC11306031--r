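test_that("triangle normal follows the edge cross product", {
  expect_equal(triangle_normal(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               c(0, 0, 1))
  expect_error(triangle_normal(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear")
  withr::with_seed(11, {
    for (i in 1:500) {
      g1 <- rnorm(3); g2 <- rnorm(3); g3 <- rnorm(3)
      n <- triangle_normal(g1, g2, g3)
      # independent cross-product oracle on the edge vectors
      oracle <- c((g2 - g1)[2] * (g3 - g1)[3] - (g2 - g1)[3] * (g3 - g1)[2],
                  (g2 - g1)[3] * (g3 - g1)[1] - (g2 - g1)[1] * (g3 - g1)[3],
                  (g2 - g1)[1] * (g3 - g1)[2] - (g2 - g1)[2] * (g3 - g1)[1])
      expect_equal(n, oracle, tolerance = 1e-12)
      # orthogonal to both edges
      expect_lt(abs(sum(n * (g2 - g1))), 1e-9 * sqrt(sum(n^2)))
      expect_lt(abs(sum(n * (g3 - g1))), 1e-9 * sqrt(sum(n^2)))
    }
  })
})

test_that("triangle centroid is the vertex mean", {
  expect_equal(triangle_centroid(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
               c(1, 1, 0))
  v <- c(2, -1, 5)
  expect_equal(triangle_centroid(v, v, v), v)
  withr::with_seed(12, {
    g1 <- rnorm(3); g2 <- rnorm(3); g3 <- rnorm(3)
    expect_equal(triangle_centroid(g1, g2, g3),
                 (g1 + g2 + g3) / 3, tolerance = 1e-12)
  })
})

test_that("circle fit is exact on noiseless circles and partial arcs", {
  th <- seq(0, 2 * pi, length.out = 51)[-51]
  fit <- fit_circle(cbind(1 + 0.02 * cos(th), 2 + 0.02 * sin(th)))
  expect_equal(fit$center, c(1, 2), tolerance = 1e-9)
  expect_equal(fit$radius, 0.02, tolerance = 1e-9)
  expect_lt(fit$rms, 1e-9)
  # half circle
  th <- seq(0, pi, length.out = 40)
  fit <- fit_circle(cbind(cos(th), sin(th)))
  expect_equal(fit$radius, 1, tolerance = 1e-9)
  expect_lt(fit$rms, 1e-9)
  # 120-degree arc
  th <- seq(0, 2 * pi / 3, length.out = 30)
  fit <- fit_circle(cbind(5 + 3 * cos(th), -2 + 3 * sin(th)))
  expect_equal(fit$center, c(5, -2), tolerance = 1e-8)
  expect_lt(fit$rms, 1e-9)
})

test_that("three-point circumcircle is solved exactly", {
  fit <- fit_circle(rbind(c(0, 0), c(2, 0), c(1, 1)))
  expect_equal(fit$center, c(1, 0), tolerance = 1e-9)
  expect_equal(fit$radius, 1, tolerance = 1e-9)
})

test_that("collinear 2D points are a degenerate circle", {
  expect_error(fit_circle(cbind(1:5, 2 * (1:5) + 1)), "collinear")
  expect_error(fit_circle(rbind(c(0, 0), c(1, 1))), "at least 3")
})
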