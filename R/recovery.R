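#' End-to-end parameter-recovery evaluation on a synthetic root system
#'
#' Generates a root system from `spec`, runs the full reconstruction
#' pipeline, and scores the result against the generator's ground truth:
#' per-order branch counts, relative errors of total length, volume and
#' lateral surface area, detection confusion via [match_roots()] on
#' attachment positions, and basal-diameter errors of matched roots
#' (each measured diameter is compared with the true diameter at the same
#' cross-section, see [truth_diameter_at()]).
#'
#' @param spec a [root_synth_spec()].
#' @param config a [root_config()]; synthetic runs use a decimeter-scale
#'   `hs`.
#' @param tol match tolerance for attachment positions (m).
#' @return a one-row tibble with detected/true counts, relative trait
#'   errors (percent), `tp`/`fp`/`fn`, `f1`, and mean/max relative
#'   basal-diameter error (percent).
#' @export
recovery_report <- function(spec,
                            config = root_config(hs = 0.05, cp = 0.003),
                            tol = 0.1) {
  gen <- generate_root_system(spec)
  res <- reconstruct_root(gen$cloud, config = config, denoise = FALSE)
  tr <- extract_traits(res$model, data = res$cloud,
                       min_basal_diameter_cm = config$min_basal_diameter_cm)
  tt <- gen$truth$traits

  det <- measure_branches(res$model, res$cloud)
  det <- dplyr::rename(det, x = "attach_x", y = "attach_y", z = "attach_z")
  counts <- match_roots(det, gen$truth$branches, tol = tol)
  f1_val <- f1(recall(counts$tp, counts$fn), precision(counts$tp, counts$fp))

  pairs <- match_root_pairs(det, gen$truth$branches, tol = tol)
  rd_err <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$det[k]
    j <- pairs$ref[k]
    td <- if (det$rd_source[i] == "cloud") {
      truth_diameter_at(gen$truth, gen$truth$branches$branch_id[j],
                        c(det$measure_x[i], det$measure_y[i],
                          det$measure_z[i]))
    } else {
      200 * gen$truth$branches$basal_radius[j]
    }
    abs(det$rd_cm[i] - td) / td
  }, numeric(1))

  count_cols <- function(x, o) {
    nm <- paste0("n_order", o)
    if (nm %in% names(x)) x[[nm]] else 0L
  }
  tibble(
    n_points = nrow(gen$cloud),
    det_order0 = count_cols(tr, 0), det_order1 = count_cols(tr, 1),
    det_order2 = count_cols(tr, 2),
    true_order0 = count_cols(tt, 0), true_order1 = count_cols(tt, 1),
    true_order2 = count_cols(tt, 2),
    length_err_pct = 100 * (tr$root_length_m / tt$root_length_m - 1),
    volume_err_pct = 100 * (tr$root_volume_m3 / tt$root_volume_m3 - 1),
    surface_err_pct = 100 * (tr$root_surface_area_m2 /
                               tt$root_surface_area_m2 - 1),
    tp = counts$tp, fp = counts$fp, fn = counts$fn,
    f1 = f1_val,
    rd_mean_err_pct = 100 * mean(rd_err),
    rd_max_err_pct = 100 * max(rd_err)
  )
}
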