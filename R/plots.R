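#' Plot an image or mask as a raster
#'
#' @param object A [gray_image()] or [binary_mask()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gray_image <- function(object, ...) {
  px <- as_pixels(object)
  df <- tidyr::expand_grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$intensity <- px[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gray_image
#' @export
autoplot.binary_mask <- function(object, ...) {
  img <- gray_image(as_pixels(object) * 255L, um_per_pixel = object$um_per_pixel)
  autoplot(img) + ggplot2::guides(fill = "none")
}

#' Percent-of-control bar chart with significance stars
#'
#' The figure style of the study: one bar per group showing the mean in
#' percent-of-control units, error bars of one SEM, and star annotations for
#' the Bonferroni/Dunn-adjusted comparison against the control group.
#'
#' @param object A `tj_group_comparison` from [compare_groups()].
#' @param control_group Control label (default `"control"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tj_group_comparison <- function(object, control_group = "control", ...) {
  tbl <- report_figure_table(object, control_group = control_group)
  tbl$group <- factor(tbl$group, levels = tbl$group)
  ggplot2::ggplot(tbl, ggplot2::aes(.data$group, .data$pct_mean)) +
    ggplot2::geom_col(fill = "grey35", width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$pct_mean - .data$pct_sem,
                   ymax = .data$pct_mean + .data$pct_sem),
      width = 0.2) +
    ggplot2::geom_text(
      ggplot2::aes(y = .data$pct_mean + .data$pct_sem, label = .data$stars),
      vjust = -0.5, size = 5) +
    ggplot2::labs(x = NULL, y = "% of control",
                  title = object$value %||% NULL) +
    ggplot2::theme_classic()
}
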