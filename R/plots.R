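#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a point cloud as 2-D projections
#'
#' Side (x–z) and top (x–y) orthographic projections, colored by height or,
#' if present, the `label` column. Projections keep the plot light for
#' clouds of 10^3–10^4 points without needing an interactive 3-D viewer.
#'
#' @param object A [point_cloud()].
#' @param color Column name to color by (default `"z"`, or `"label"` when
#'   present).
#' @param size Point size.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot point_cloud
#' @export
autoplot.point_cloud <- function(object, color = NULL,
                                 size = 0.3, ...) {
  color <- color %||% (if ("label" %in% names(object)) "label" else "z")
  df <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    dplyr::mutate(df, h = .data$x, v = .data$z, view = "side (x-z)"),
    dplyr::mutate(df, h = .data$x, v = .data$y, view = "top (x-y)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$h, .data$v,
                                     color = .data[[color]])) +
    ggplot2::geom_point(size = size) +
    ggplot2::facet_wrap(~view, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot training-loss curves
#'
#' Loss components per epoch on a log scale, plus the learning-rate
#' schedule as a secondary panel.
#'
#' @param object A `denoise_fit` from [train_denoiser()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot denoise_fit
#' @export
autoplot.denoise_fit <- function(object, ...) {
  h <- object$history
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, value = h$l_mse, what = "l_mse"),
    tibble::tibble(epoch = h$epoch, value = h$total, what = "total"),
    tibble::tibble(epoch = h$epoch, value = h$lr, what = "learning rate"))
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Compare metric reports visually
#'
#' Bar chart of the four metrics for the noisy versus denoised cloud.
#'
#' @param report A `metric_report` from [evaluate_denoising()].
#' @return A ggplot object.
#' @export
plot_metric_report <- function(report) {
  stopifnot(inherits(report, "metric_report"))
  long <- tibble::as_tibble(report) |>
    tidyr_longer(c("mse", "snr_db", "hausdorff", "ssim"))
  ggplot2::ggplot(long, ggplot2::aes(.data$cloud, .data$value,
                                     fill = .data$cloud)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

tidyr_longer <- function(df, cols) {
  out <- purrr::map(cols, function(cn) {
    tibble::tibble(cloud = df$cloud, metric = cn, value = df[[cn]])
  })
  dplyr::bind_rows(out)
}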