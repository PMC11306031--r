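#' Agreement statistics for paired measurements
#'
#' The regression-style accuracy statistics used to compare estimated root
#' diameters against caliper references: coefficient of determination
#' `R2 = 1 - SSE/SST`, root-mean-square error, relative RMSE (percent of the
#' reference mean), and mean absolute error.
#'
#' @param x numeric vector of measured (reference) values.
#' @param x_hat numeric vector of estimated values, same length.
#' @return a single number; `rrmse()` is in percent.
#' @name paired-metrics
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))
#' rmse(c(4, 6), c(5, 5))
NULL

check_paired <- function(x, x_hat, min_n = 1) {
  if (length(x) != length(x_hat)) {
    abort("paired metrics: `x` and `x_hat` differ in length.")
  }
  if (length(x) < min_n) {
    abort(paste0("paired metrics: need at least ", min_n, " pairs."))
  }
  if (!all(is.finite(x)) || !all(is.finite(x_hat))) {
    abort("paired metrics: values must be finite.")
  }
}

#' @rdname paired-metrics
#' @export
r_squared <- function(x, x_hat) {
  check_paired(x, x_hat, min_n = 2)
  sst <- sum((x - mean(x))^2)
  if (sst == 0) abort("r_squared: `x` is constant; variance undefined.")
  1 - sum((x - x_hat)^2) / sst
}

#' @rdname paired-metrics
#' @export
rmse <- function(x, x_hat) {
  check_paired(x, x_hat)
  sqrt(mean((x - x_hat)^2))
}

#' @rdname paired-metrics
#' @export
rrmse <- function(x, x_hat) {
  check_paired(x, x_hat)
  if (mean(x) == 0) abort("rrmse: mean of `x` is zero.")
  rmse(x, x_hat) / mean(x) * 100
}

#' @rdname paired-metrics
#' @export
mae <- function(x, x_hat) {
  check_paired(x, x_hat)
  mean(abs(x_hat - x))
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length (n >= 2), neither constant.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  check_paired(x, y, min_n = 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("pearson_r: a constant vector has no defined correlation.")
  }
  stats::cor(x, y, method = "pearson")
}

#' Detection metrics from confusion counts
#'
#' Standard detection bookkeeping over true/false positives/negatives.
#' `accuracy()` needs true negatives, which only exist when an explicit
#' candidate universe is defined; calling it with `tn = NA` is an error
#' rather than a silent zero.
#'
#' @param tp,fp,fn,tn nonnegative counts.
#' @param recall,precision values in `[0, 1]` for `f1()`.
#' @return a single number in `[0, 1]`.
#' @name detection-metrics
#' @examples
#' f1(recall = 0.76, precision = 0.83)
NULL

#' @rdname detection-metrics
#' @export
recall <- function(tp, fn) {
  if (tp + fn == 0) abort("recall: TP + FN is zero; recall undefined.")
  tp / (tp + fn)
}

#' @rdname detection-metrics
#' @export
precision <- function(tp, fp) {
  if (tp + fp == 0) abort("precision: TP + FP is zero; precision undefined.")
  tp / (tp + fp)
}

#' @rdname detection-metrics
#' @export
f1 <- function(recall, precision) {
  if (recall + precision == 0) abort("f1: recall + precision is zero.")
  2 * recall * precision / (recall + precision)
}

#' @rdname detection-metrics
#' @export
accuracy <- function(tp, tn, fp, fn) {
  if (any(is.na(c(tp, tn, fp, fn)))) {
    abort("accuracy: TN (or another count) is unavailable; accuracy needs a closed candidate universe.")
  }
  denom <- tp + tn + fp + fn
  if (denom == 0) abort("accuracy: all counts are zero.")
  (tp + tn) / denom
}

#' Match detected roots against a reference set
#'
#' Greedy one-to-one matching: same-order detected/reference pairs are
#' matched closest-first by basal-position distance, accepting pairs within
#' `tol` meters. Matched pairs are true positives, unmatched detections
#' false positives, unmatched references false negatives. True negatives are
#' only defined when `n_universe` supplies a closed candidate universe
#' (then `TN = n_universe - TP - FP - FN`), otherwise `NA`.
#'
#' @param detected,reference data frames with columns `order`, `x`, `y`, `z`
#'   (basal/attachment position, m).
#' @param tol match tolerance in meters (> 0).
#' @param n_universe optional candidate-universe size for TN.
#' @return a one-row tibble: `tp`, `fp`, `fn`, `tn`.
#' @export
match_roots <- function(detected, reference, tol, n_universe = NA) {
  if (tol <= 0) abort("match_roots: `tol` must be > 0.")
  need <- c("order", "x", "y", "z")
  stopifnot(all(need %in% names(detected)), all(need %in% names(reference)))
  tp <- 0L
  used_d <- rep(FALSE, nrow(detected))
  used_r <- rep(FALSE, nrow(reference))
  for (o in sort(unique(c(detected$order, reference$order)))) {
    di <- which(detected$order == o)
    ri <- which(reference$order == o)
    if (length(di) == 0 || length(ri) == 0) next
    dd <- outer(seq_along(di), seq_along(ri), function(a, b) {
      sqrt((detected$x[di[a]] - reference$x[ri[b]])^2 +
           (detected$y[di[a]] - reference$y[ri[b]])^2 +
           (detected$z[di[a]] - reference$z[ri[b]])^2)
    })
    repeat {
      if (all(!is.finite(dd)) || min(dd, na.rm = TRUE) > tol) break
      k <- arrayInd(which.min(dd), dim(dd))
      tp <- tp + 1L
      used_d[di[k[1]]] <- TRUE
      used_r[ri[k[2]]] <- TRUE
      dd[k[1], ] <- Inf
      dd[, k[2]] <- Inf
    }
  }
  fp <- sum(!used_d)
  fn <- sum(!used_r)
  tn <- if (is.na(n_universe)) NA_integer_ else
    as.integer(n_universe) - tp - fp - fn
  tibble(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Detection report from confusion counts
#'
#' @param counts a one-row tibble from [match_roots()] (or any `tp/fp/fn/tn`
#'   row set, e.g. one row per branching order).
#' @param digits table rounding (half-up), default 2 as in published
#'   accuracy tables; use `NULL` for full precision.
#' @return tibble with recall, precision, F1 and (when TN is defined)
#'   accuracy per input row.
#' @export
detection_report <- function(counts, digits = 2) {
  out <- dplyr::mutate(
    as_tibble(counts),
    recall = recall(.data$tp, .data$fn),
    precision = precision(.data$tp, .data$fp),
    f1 = f1(.data$recall, .data$precision),
    accuracy = ifelse(is.na(.data$tn), NA_real_,
                      (.data$tp + .data$tn) /
                        (.data$tp + .data$tn + .data$fp + .data$fn))
  )
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(
      c("recall", "precision", "f1", "accuracy"),
      ~ round_half_up(.x, digits)))
  }
  out
}

#' Regression-style accuracy report for paired diameters
#'
#' @param data a data frame.
#' @param truth,estimate column names (unquoted) of reference and estimated
#'   values.
#' @return a one-row tibble with n, R2, RMSE, rRMSE (%), MAE, Pearson r and
#'   a two-sided t-approximation p-value for r (labelled as such).
#' @export
regression_report <- function(data, truth, estimate) {
  x <- dplyr::pull(data, {{ truth }})
  xh <- dplyr::pull(data, {{ estimate }})
  n <- length(x)
  r <- pearson_r(x, xh)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  tibble(
    n = n,
    r_squared = r_squared(x, xh),
    rmse = rmse(x, xh),
    rrmse_pct = rrmse(x, xh),
    mae = mae(x, xh),
    pearson_r = r,
    p_value_t_approx = 2 * stats::pt(-abs(tstat), df = n - 2)
  )
}
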