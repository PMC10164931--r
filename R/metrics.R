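#' Ground truth by replicate averaging
#'
#' Averages aligned noisy replicates voxelwise into a single low-noise
#' reference stack and quantizes it to the input bit depth. Averaging n
#' replicates reduces Gaussian noise variance n-fold, i.e. a
#' `10 * log10(n)` dB PSNR gain over a single replicate.
#'
#' @param aligned_replicates list of >= 2 `stack5d` objects with identical
#'   geometry (e.g. the output of [align_replicates_translation()]).
#' @return integer `stack5d` of the common geometry.
#' @export
generate_ground_truth <- function(aligned_replicates) {
  stopifnot(is.list(aligned_replicates), length(aligned_replicates) >= 2L)
  ref <- aligned_replicates[[1]]
  validate_stack5d(ref)
  d <- dim(ref$data)
  acc <- array(0, d)
  for (k in seq_along(aligned_replicates)) {
    s <- aligned_replicates[[k]]
    if (!all(dim(s$data) == d)) {
      stop("replicate ", k, " geometry differs from replicate 1", call. = FALSE)
    }
    acc <- acc + s$data
  }
  acc <- acc / length(aligned_replicates)
  bd <- if (ref$is_float) 16L else ref$bit_depth
  suppressMessages(quantize_to_uint(
    stack_like(ref, acc, bit_depth = 32L, is_float = TRUE), bd))
}

#' Image quality metrics against a reference
#'
#' `MSE = mean((ref - test)^2)`, `RMSE = sqrt(MSE)`, `MAE = mean(|ref -
#' test|)`, `PSNR = 10 * log10(peak^2 / MSE)` in dB. By default `peak` is the
#' maximum of the reference image; `peak = "range"` uses the full bit-depth
#' maximum instead (pass it via `peak_value`). Identical images give RMSE 0
#' and infinite PSNR (flagged, not an error).
#'
#' @param reference,test 2D numeric matrices of equal shape.
#' @param peak_value optional fixed peak (e.g. `2^16 - 1`); default
#'   `max(reference)`.
#' @return one-row tibble with `psnr_db`, `rmse`, `mae`, `identical`.
#' @export
image_metrics <- function(reference, test, peak_value = NULL) {
  if (!all(dim(reference) == dim(test))) {
    stop("reference and test shapes differ", call. = FALSE)
  }
  err <- reference - test
  mse <- mean(err^2)
  peak <- if (is.null(peak_value)) max(reference) else peak_value
  tibble::tibble(
    psnr_db = if (mse == 0) Inf else 10 * log10(peak^2 / mse),
    rmse = sqrt(mse),
    mae = mean(abs(err)),
    identical = mse == 0)
}

#' Denoiser benchmark against an averaged ground truth
#'
#' For every method (plus the raw input), time point, slice and channel,
#' computes [image_metrics()] of the corresponding slice against the ground
#' truth slice. With 25 time points and 45 slices this yields n = 1,125 PSNR
#' values per channel per method.
#'
#' @param validation list of noisy `stack5d` time points (single time point
#'   each).
#' @param gt ground-truth `stack5d` (single time point) with matching
#'   `(z, c, y, x)`.
#' @param methods named list of denoiser functions, each taking and returning
#'   a `stack5d` (e.g. `list(vst3d = function(s) denoise_vst(s))`). The raw
#'   input is always benchmarked as method `"raw"`.
#' @param peak_value optional fixed PSNR peak; default per-slice reference
#'   max.
#' @return list of class `metrics_report`: `rows` (tibble `method, channel,
#'   timepoint, slice, psnr_db, rmse, mae`) and `summary` (tibble `method,
#'   channel, mean_psnr, sd_psnr, n`).
#' @export
benchmark_denoisers <- function(validation, gt, methods, peak_value = NULL) {
  stopifnot(is.list(validation), length(validation) >= 1L)
  validate_stack5d(gt)
  dg <- dim(gt$data)
  all_methods <- c(list(raw = identity), methods)
  rows <- vector("list", length(all_methods) * length(validation))
  ri <- 1L
  for (mi in seq_along(all_methods)) {
    mname <- names(all_methods)[mi]
    fn <- all_methods[[mi]]
    for (ti in seq_along(validation)) {
      den <- fn(validation[[ti]])
      d <- dim(den$data)
      if (!all(d[c(2, 3, 4, 5)] == dg[c(2, 3, 4, 5)])) {
        stop("geometry of method '", mname, "' output differs from ground truth",
             call. = FALSE)
      }
      n_sl <- d[2] * d[3]
      psnr <- rmse <- mae <- numeric(n_sl)
      ch <- integer(n_sl); sl <- integer(n_sl)
      k <- 1L
      for (ci in seq_len(d[3])) for (zi in seq_len(d[2])) {
        m <- image_metrics(matrix(gt$data[1, zi, ci, , ], dg[4], dg[5]),
                           matrix(den$data[1, zi, ci, , ], d[4], d[5]),
                           peak_value = peak_value)
        psnr[k] <- m$psnr_db; rmse[k] <- m$rmse; mae[k] <- m$mae
        ch[k] <- ci; sl[k] <- zi
        k <- k + 1L
      }
      rows[[ri]] <- tibble::tibble(
        method = mname, channel = gt$channel_names[ch], timepoint = ti,
        slice = sl, psnr_db = psnr, rmse = rmse, mae = mae)
      ri <- ri + 1L
    }
  }
  rows <- do.call(rbind, rows)
  agg <- stats::aggregate(psnr_db ~ method + channel, data = rows,
                          FUN = function(v) c(mean = mean(v[is.finite(v)]),
                                              sd = stats::sd(v[is.finite(v)]),
                                              n = length(v)))
  summary <- tibble::tibble(
    method = agg$method, channel = agg$channel,
    mean_psnr = agg$psnr_db[, "mean"], sd_psnr = agg$psnr_db[, "sd"],
    n = as.integer(agg$psnr_db[, "n"]))
  structure(list(rows = rows, summary = summary), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$summary)
  invisible(x)
}

#' Build an ROI set from binary masks
#'
#' The merged mask is the voxelwise Boolean OR of the individual masks, so
#' overlapping pixels are counted once in any measurement over the union.
#'
#' @param masks list of logical (or 0/1) matrices on the frame grid.
#' @return object of class `roi_set` with elements `masks` and `union`.
#' @export
roi_set <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  d <- dim(masks[[1]])
  u <- matrix(FALSE, d[1], d[2])
  for (m in masks) {
    if (!all(dim(m) == d)) stop("mask shapes differ", call. = FALSE)
    u <- u | (m != 0)
  }
  structure(list(masks = masks, union = u), class = "roi_set")
}

#' Mean-intensity time course over a merged ROI
#'
#' @param tseries a `stack5d` time series (Z = 1 or a chosen z handled by the
#'   caller; the first z plane is used).
#' @param rois a [roi_set()] whose masks match the frame grid.
#' @param channel 1-based channel index.
#' @return tibble with `frame`, `time_s`, `mean_intensity` over the union
#'   mask.
#' @export
roi_timecourse <- function(tseries, rois, channel = 1L) {
  validate_stack5d(tseries)
  stopifnot(inherits(rois, "roi_set"))
  d <- dim(tseries$data)
  if (!all(dim(rois$union) == d[4:5])) {
    stop("ROI masks do not match the frame geometry", call. = FALSE)
  }
  if (!any(rois$union)) stop("empty ROI union", call. = FALSE)
  vals <- vapply(seq_len(d[1]), function(ti) {
    fr <- matrix(tseries$data[ti, 1, channel, , ], d[4], d[5])
    mean(fr[rois$union])
  }, numeric(1))
  tibble::tibble(frame = seq_len(d[1]),
                 time_s = (seq_len(d[1]) - 1) * tseries$frame_interval,
                 mean_intensity = vals)
}
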