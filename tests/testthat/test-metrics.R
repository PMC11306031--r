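test_that("R2, RMSE, rRMSE and MAE match hand evaluations", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_equal(rmse(c(4, 6), c(5, 5)), 1)
  expect_equal(mae(c(4, 6), c(5, 5)), 1)
  expect_equal(rrmse(c(4, 6), c(5, 5)), 20)
  x <- c(1.2, 3.4, 5.6)
  expect_equal(rmse(x, x), 0)
  expect_equal(mae(x, x), 0)
  expect_equal(rrmse(x, x), 0)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(rrmse(c(-1, 1), c(0, 0)), "zero")
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("RMSE dominates MAE and metrics ignore sample order", {
  withr::with_seed(21, {
    for (i in 1:200) {
      n <- sample(2:50, 1)
      x <- rnorm(n); xh <- rnorm(n)
      expect_gte(rmse(x, xh), mae(x, xh) - 1e-12)
      p <- sample(n)
      expect_equal(rmse(x[p], xh[p]), rmse(x, xh))
      expect_equal(mae(x[p], xh[p]), mae(x, xh))
    }
  })
})

test_that("Pearson r matches hand evaluation and hits the bounds", {
  x <- rnorm(20)
  expect_equal(pearson_r(x, 2 * x + 3), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("R2 equals squared Pearson r for the least-squares line", {
  withr::with_seed(22, {
    for (i in 1:20) {
      x <- rnorm(30)
      y <- 2 * x + rnorm(30)
      fitted <- fitted(lm(y ~ x))
      expect_equal(r_squared(y, fitted), pearson_r(x, y)^2,
                   tolerance = 1e-10)
    }
  })
})

test_that("detection metrics follow their closed forms", {
  expect_equal(f1(1, 1), 1)
  expect_equal(recall(3, 1), 0.75)
  expect_equal(precision(3, 1), 0.75)
  expect_equal(accuracy(3, 2, 1, 1), 5 / 7)
  expect_error(accuracy(3, NA, 1, 1), "universe")
  expect_error(recall(0, 0), "undefined")
  expect_error(f1(0, 0), "zero")
  # harmonic mean bounds
  withr::with_seed(23, {
    for (i in 1:100) {
      r <- runif(1, 0.05, 1); p <- runif(1, 0.05, 1)
      f <- f1(r, p)
      expect_gte(f, min(r, p) - 1e-12)
      expect_lte(f, max(r, p) + 1e-12)
    }
  })
})

test_that("greedy root matching counts TP/FP/FN correctly", {
  ref <- tibble::tibble(order = c(1, 1, 2), x = c(0, 1, 2), y = 0, z = 0)
  expect_equal(match_roots(ref, ref, tol = 0.05),
               tibble::tibble(tp = 3L, fp = 0L, fn = 0L, tn = NA_integer_))
  none <- ref[0, ]
  expect_equal(match_roots(none, ref, tol = 0.05)$fn, 3L)
  # one detection displaced by twice the tolerance
  det <- ref
  det$x[2] <- det$x[2] + 0.1
  cm <- match_roots(det, ref, tol = 0.05)
  expect_equal(unlist(cm[, 1:3], use.names = FALSE), c(2L, 1L, 1L))
  # symmetric under swapping roles
  cm2 <- match_roots(ref, det, tol = 0.05)
  expect_equal(cm2$fp, cm$fn)
  expect_equal(cm2$fn, cm$fp)
  # order labels must agree even at zero distance
  det2 <- ref
  det2$order <- c(2, 2, 1)
  expect_equal(match_roots(det2, ref, tol = 0.05)$tp, 0L)
  # closed universe defines TN
  expect_equal(match_roots(ref, ref, tol = 0.05, n_universe = 10)$tn, 7L)
})

test_that("reports round half-up at two decimals like published tables", {
  expect_equal(round_half_up(0.835, 2), 0.84)
  expect_equal(round_half_up(0.79346, 2), 0.79)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  rep <- detection_report(tibble::tibble(tp = 19, fp = 4, fn = 6,
                                         tn = NA_integer_))
  expect_equal(rep$recall, round_half_up(19 / 25, 2))
  expect_true(is.na(rep$accuracy))
})

test_that("regression_report aggregates the paired statistics", {
  d <- tibble::tibble(truth = c(1, 2, 3, 4), est = c(1.1, 1.9, 3.2, 3.8))
  out <- regression_report(d, truth, est)
  expect_equal(out$n, 4)
  expect_equal(out$rmse, rmse(d$truth, d$est))
  expect_equal(out$pearson_r, pearson_r(d$truth, d$est))
  expect_lt(out$p_value_t_approx, 0.05)
})
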