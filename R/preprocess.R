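#' Statistical outlier removal
#'
#' Classic statistical outlier removal (SOR): for every point, compute the
#' mean distance to its `k` nearest neighbours; keep the point iff that
#' statistic is at most `mean + std_ratio * sd` of the statistic over the
#' whole cloud. Isolated returns (soil debris, ghost points) sit far from
#' the root surface and are dropped; the dense surface is untouched.
#'
#' @param data a cloud tibble.
#' @param k number of neighbours for the distance statistic (>= 3).
#' @param std_ratio keep threshold in standard deviations (> 0).
#' @return the filtered cloud (a subset of the input rows).
#' @export
remove_outliers <- function(data, k = 8, std_ratio = 2.0) {
  data <- as_cloud(data)
  k <- as.integer(k)
  if (k < 3) abort("remove_outliers: `k` must be >= 3.")
  if (std_ratio <= 0) abort("remove_outliers: `std_ratio` must be > 0.")
  if (nrow(data) <= k) {
    abort(paste0("remove_outliers: cloud has ", nrow(data),
                 " points; need more than k = ", k, "."))
  }
  nn <- .knn_cpp(cloud_matrix(data), k)
  md <- rowMeans(nn$dist)
  # small epsilon so a perfectly regular cloud (sd ~ 0) is never culled
  thr <- mean(md) + std_ratio * stats::sd(md) + 1e-12
  data[md <= thr, , drop = FALSE]
}

#' Voxel-grid thinning controlled by the cloud parameter (CP)
#'
#' Down-samples the cloud on a cubic voxel grid of edge `cp` meters,
#' retaining at most one *original* point per occupied voxel — the member
#' nearest the voxel centroid (ties broken by lowest point index). Keeping a
#' real surface point rather than the centroid avoids pulling points off the
#' root surface, which would bias cylinder radii. `cp = 0` disables thinning.
#' The voxel grid is anchored at a fixed origin (0,0,0) so sweeps over CP
#' values are nested consistently.
#'
#' @param data a cloud tibble.
#' @param cp voxel edge length in meters (>= 0); the "cloud parameter".
#' @return the thinned cloud (a subset of the input rows).
#' @export
downsample_cp <- function(data, cp = 0.003) {
  data <- as_cloud(data)
  if (!is.numeric(cp) || length(cp) != 1 || is.na(cp) || cp < 0) {
    abort("downsample_cp: `cp` must be a single number >= 0.")
  }
  if (cp == 0) return(data)
  ix <- floor(data$x / cp)
  iy <- floor(data$y / cp)
  iz <- floor(data$z / cp)
  key <- paste(ix, iy, iz)
  # squared distance to the centroid of the occupied voxel
  cx <- stats::ave(data$x, key); cy <- stats::ave(data$y, key)
  cz <- stats::ave(data$z, key)
  d2 <- (data$x - cx)^2 + (data$y - cy)^2 + (data$z - cz)^2
  ord <- order(key, d2, seq_len(nrow(data)))
  keep <- ord[!duplicated(key[ord])]
  data[sort(keep), , drop = FALSE]
}
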