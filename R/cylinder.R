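#' Fit a cylinder to 3D points by nonlinear least squares
#'
#' Minimizes the sum of squared orthogonal residuals `(d_i - r)^2`, where
#' `d_i` is the distance of point `i` to the cylinder axis, over the axis
#' position, axis direction and radius. The axis is parameterized by two
#' in-plane offsets of its anchor point and two tilt components relative to
#' the initial direction, which keeps the problem well-posed (translations
#' along the axis and spin about it are quotiented out). Optimization is
#' Levenberg-Marquardt damped least squares
#' (relative tolerance 1e-8, at most 200 iterations).
#'
#' @param points an n x 3 matrix or data frame of surface points (m), n >= 7,
#'   not collinear.
#' @param init_axis a list with `point` (3-vector on the initial axis) and
#'   `direction` (3-vector, need not be unit length), typically a skeleton
#'   edge.
#' @return an object of class `cylinder_fit`: list with `start`, `end`
#'   (extreme projections of the points onto the fitted axis), `axis` (unit
#'   vector), `radius` (m), `rmse_fit` (m), `n_points`, `iterations`,
#'   `converged`.
#' @export
fit_cylinder <- function(points, init_axis) {
  if (is.data.frame(points)) points <- cloud_matrix(points)
  points <- as.matrix(points)
  if (ncol(points) != 3) abort("fit_cylinder: `points` must be n x 3.")
  n <- nrow(points)
  if (n < 7) abort(paste0("fit_cylinder: need at least 7 points, got ", n, "."))
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr), nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12)) {
    abort("fit_cylinder: points are (near-)collinear; cylinder is degenerate.")
  }
  u0 <- init_axis$direction
  if (vnorm(u0) <= 0) abort("fit_cylinder: zero-length initial direction.")
  u0 <- u0 / vnorm(u0)
  a0 <- as.numeric(init_axis$point)
  # orthonormal basis of the plane normal to u0
  e1 <- if (abs(u0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * u0) * u0; e1 <- e1 / vnorm(e1)
  e2 <- c(u0[2] * e1[3] - u0[3] * e1[2],
          u0[3] * e1[1] - u0[1] * e1[3],
          u0[1] * e1[2] - u0[2] * e1[1])

  axis_dist <- function(par) {
    u <- u0 + par[3] * e1 + par[4] * e2
    u <- u / vnorm(u)
    a <- a0 + par[1] * e1 + par[2] * e2
    q <- sweep(points, 2, a)
    t <- q %*% u
    sqrt(pmax(rowSums(q^2) - t^2, 0))
  }
  r0 <- stats::median(axis_dist(c(0, 0, 0, 0)))
  if (r0 <= 0) r0 <- 1e-4
  fit <- minpack.lm::nls.lm(
    par = c(0, 0, 0, 0, r0),
    fn = function(par) axis_dist(par) - par[5],
    control = minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                         maxiter = 200)
  )
  if (fit$info == 0 || fit$info == 5) {
    abort(paste0("fit_cylinder: no convergence after ", fit$niter,
                 " iterations (last RMSE ",
                 signif(sqrt(mean(fit$fvec^2)), 4), " m)."))
  }
  par <- fit$par
  u <- u0 + par[3] * e1 + par[4] * e2; u <- u / vnorm(u)
  a <- a0 + par[1] * e1 + par[2] * e2
  r <- par[5]
  if (!is.finite(r) || r <= 0) abort("fit_cylinder: fit collapsed to non-positive radius.")
  t <- sweep(points, 2, a) %*% u
  res <- axis_dist(par) - r
  structure(list(
    start = a + min(t) * u,
    end = a + max(t) * u,
    axis = u,
    radius = r,
    rmse_fit = sqrt(mean(res^2)),
    n_points = n,
    iterations = fit$niter,
    converged = TRUE
  ), class = "cylinder_fit")
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat("<cylinder_fit> radius ", signif(x$radius, 5), " m, length ",
      signif(vnorm(x$end - x$start), 5), " m, rmse ",
      signif(x$rmse_fit, 3), " m (", x$n_points, " points)\n", sep = "")
  invisible(x)
}

#' @rdname fit_cylinder
#' @param x a `cylinder_fit`.
#' @param ... unused.
#' @export
tidy.cylinder_fit <- function(x, ...) {
  tibble(
    start_x = x$start[1], start_y = x$start[2], start_z = x$start[3],
    end_x = x$end[1], end_y = x$end[2], end_z = x$end[3],
    axis_x = x$axis[1], axis_y = x$axis[2], axis_z = x$axis[3],
    radius = x$radius, length = vnorm(x$end - x$start),
    rmse_fit = x$rmse_fit
  )
}

#' @rdname fit_cylinder
#' @export
glance.cylinder_fit <- function(x, ...) {
  tibble(n_points = x$n_points, rmse_fit = x$rmse_fit,
         iterations = x$iterations, converged = x$converged)
}
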