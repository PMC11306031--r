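#' Round half away from zero
#'
#' Fixed-precision rounding that resolves ties away from zero (0.005 -> 0.01),
#' the convention used in published trait and accuracy tables. Base R's
#' `round()` rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
#' @examples
#' round_half_up(0.835, 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Validate and coerce a cloud-like data frame: needs numeric, finite x/y/z.
as_cloud <- function(data, allow_empty = FALSE) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with columns x, y, z.")
  }
  miss <- setdiff(c("x", "y", "z"), names(data))
  if (length(miss)) {
    abort(paste0("cloud is missing coordinate column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!allow_empty && nrow(data) < 1) {
    abort("empty point cloud: at least one point is required.")
  }
  xyz <- as.matrix(data[, c("x", "y", "z")])
  if (nrow(data) > 0 && !all(is.finite(xyz))) {
    abort("cloud contains non-finite coordinates (NaN/Inf).")
  }
  as_tibble(data)
}

cloud_matrix <- function(data) {
  unname(as.matrix(data[, c("x", "y", "z")]))
}

vnorm <- function(v) sqrt(sum(v^2))

# Rotation matrix sending unit vector `from` onto unit vector `to`
# (Rodrigues). Degenerate antiparallel case handled via an arbitrary
# perpendicular axis.
rotation_between <- function(from, to) {
  f <- from / vnorm(from)
  t <- to / vnorm(to)
  v <- c(f[2] * t[3] - f[3] * t[2],
         f[3] * t[1] - f[1] * t[3],
         f[1] * t[2] - f[2] * t[1])
  c_ <- sum(f * t)
  s <- vnorm(v)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to f
    p <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a <- p - sum(p * f) * f
    a <- a / vnorm(a)
    K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
                byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

# Deterministic derived seed kept inside 32-bit integer range.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 1009 + salt * 9973) %% 2147483647)
}
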