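# ggplot2 visualization of result objects

#' Plot a super-resolution image
#'
#' @param object An `sr_image` from [render()].
#' @param trans Intensity transform for display (`"sqrt"` is standard for
#'   SR renderings; use `"identity"` for raw density).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sr_image
#' @export
autoplot.sr_image <- function(object, trans = "sqrt", ...) {
  df <- expand.grid(
    x = object$extent[1] + (seq_len(ncol(object$img)) - 0.5) / object$zoom,
    y = object$extent[3] + (seq_len(nrow(object$img)) - 0.5) / object$zoom
  )
  df$value <- as.vector(t(object$img))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "density") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (camera px)", y = "y (camera px)") +
    ggplot2::theme_minimal()
}

#' Plot an invader time-course fit
#'
#' @param object A `trace_fit` from [fit_trace()].
#' @param ... Unused.
#' @return A ggplot of the normalized trace with the fitted model and the
#'   invader addition time.
#' @method autoplot trace_fit
#' @export
autoplot.trace_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(.data$time_s,
                                    .data$normalized_intensity)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "normalized intensity") +
    ggplot2::theme_minimal()
  if (object$converged) {
    p <- p +
      ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "red") +
      ggplot2::geom_vline(xintercept = object$model$t_invader,
                          linetype = "dashed")
  }
  p
}

#' Plot per-round localization counts
#'
#' Bar chart of accepted localization counts per imaging round, colored by
#' target — the relabeling-robustness summary of a sequential experiment.
#'
#' @param report An `experiment_report` from [run_experiment()], or the
#'   `counts` tibble from [round_counts()].
#' @return A ggplot.
#' @export
plot_round_counts <- function(report) {
  counts <- if (inherits(report, "experiment_report")) report$round_counts
  else report
  ggplot2::ggplot(counts,
                  ggplot2::aes(factor(.data$round), .data$n,
                               fill = factor(.data$target_id))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "imaging round", y = "accepted localizations",
                  fill = "target") +
    ggplot2::theme_minimal()
}
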