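#' Boxplot of per-slice PSNR by method and channel
#'
#' @param report a `metrics_report` from [benchmark_denoisers()].
#' @return a ggplot object.
#' @export
plot_psnr <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  rows <- report$rows[is.finite(report$rows$psnr_db), ]
  ggplot2::ggplot(rows, ggplot2::aes(x = method, y = psnr_db, fill = method)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = NULL, y = "PSNR (dB)") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' Plot an estimated translation series
#'
#' @param series a `translation_series` tibble from [estimate_translations()].
#' @return a ggplot object with dx/dy traces over frames; flagged frames are
#'   marked.
#' @export
plot_shifts <- function(series) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  long <- rbind(
    data.frame(frame = series$frame, shift_px = series$dx, axis = "dx",
               flagged = series$flagged),
    data.frame(frame = series$frame, shift_px = series$dy, axis = "dy",
               flagged = series$flagged))
  ggplot2::ggplot(long, ggplot2::aes(x = frame, y = shift_px, colour = axis)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = long[long$flagged, ], shape = 4) +
    ggplot2::labs(y = "correction (px)") +
    ggplot2::theme_bw()
}

#' Generic for broom-style tidying (re-exported minimal generic)
#' @param x object to tidy.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")
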