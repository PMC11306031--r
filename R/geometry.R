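#' Normal vector of a triangle
#'
#' Componentwise cross product of the edge vectors `G1G2` and `G1G3` of a
#' triangulated-irregular-network (TIN) facet with vertices `G1`, `G2`,
#' `G3`: the returned vector `(A, B, C)` is orthogonal to the facet and its
#' norm equals twice the triangle area.
#'
#' @param g1,g2,g3 numeric 3-vectors, the triangle vertices.
#' @return numeric 3-vector `(A, B, C)`.
#' @export
#' @examples
#' triangle_normal(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
triangle_normal <- function(g1, g2, g3) {
  stopifnot(length(g1) == 3, length(g2) == 3, length(g3) == 3)
  a <- (g2[2] - g1[2]) * (g3[3] - g1[3]) - (g2[3] - g1[3]) * (g3[2] - g1[2])
  b <- (g2[3] - g1[3]) * (g3[1] - g1[1]) - (g2[1] - g1[1]) * (g3[3] - g1[3])
  c_ <- (g2[1] - g1[1]) * (g3[2] - g1[2]) - (g2[2] - g1[2]) * (g3[1] - g1[1])
  n <- c(a, b, c_)
  if (vnorm(n) == 0) {
    abort("triangle_normal: vertices are collinear (degenerate triangle).")
  }
  n
}

#' Centroid of a triangle
#'
#' Arithmetic mean of the three vertices.
#'
#' @inheritParams triangle_normal
#' @return numeric 3-vector.
#' @export
triangle_centroid <- function(g1, g2, g3) {
  stopifnot(length(g1) == 3, length(g2) == 3, length(g3) == 3)
  (g1 + g2 + g3) / 3
}

#' Least-squares circle fit
#'
#' Algebraic (Kasa) least-squares circle through 2D points — solving the
#' linear system for `x^2 + y^2 + D x + E y + F = 0` — followed by one
#' geometric Gauss-Newton refinement pass on the radial residuals
#' `d_i - r`. Exact on noiseless circular data including partial arcs.
#'
#' @param points2d an n x 2 matrix or data frame (columns x, y), n >= 3,
#'   not collinear.
#' @return an object of class `circle_fit`: list with `center` (2-vector),
#'   `radius`, `rms` (root-mean-square radial residual), `n_points`.
#' @export
#' @examples
#' th <- seq(0, pi, length.out = 50)
#' fit_circle(cbind(1 + 0.02 * cos(th), 2 + 0.02 * sin(th)))
fit_circle <- function(points2d) {
  p <- as.matrix(points2d)
  if (ncol(p) != 2) abort("fit_circle: `points2d` must be n x 2.")
  n <- nrow(p)
  if (n < 3) abort("fit_circle: need at least 3 points.")
  x <- p[, 1]; y <- p[, 2]
  A <- cbind(x, y, 1)
  rhs <- -(x^2 + y^2)
  qrA <- qr(A)
  if (qrA$rank < 3) {
    abort("fit_circle: points are collinear (degenerate circle).")
  }
  sol <- qr.coef(qrA, rhs)
  cx <- -sol[1] / 2; cy <- -sol[2] / 2
  r2 <- cx^2 + cy^2 - sol[3]
  if (!is.finite(r2) || r2 <= 0) abort("fit_circle: degenerate algebraic solution.")
  r <- sqrt(r2)
  # one Gauss-Newton pass on (cx, cy, r)
  for (pass in 1) {
    dx <- x - cx; dy <- y - cy
    d <- sqrt(dx^2 + dy^2)
    if (any(d < 1e-12)) break
    J <- cbind(-dx / d, -dy / d, -1)
    res <- d - r
    step <- tryCatch(qr.coef(qr(J), -res), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
  }
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  structure(list(center = unname(c(cx, cy)), radius = unname(r),
                 rms = unname(sqrt(mean((d - r)^2))), n_points = n),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat("<circle_fit> center (", signif(x$center[1], 5), ", ",
      signif(x$center[2], 5), "), radius ", signif(x$radius, 5),
      ", rms ", signif(x$rms, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_circle
#' @param x a `circle_fit`.
#' @param ... unused.
#' @export
tidy.circle_fit <- function(x, ...) {
  tibble(center_x = x$center[1], center_y = x$center[2],
         radius = x$radius, rms = x$rms, n_points = x$n_points)
}
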