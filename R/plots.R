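# ggplot2 views of the measurement tables, following the experiment's plotting
# conventions: boxes at the 25th/75th percentiles with the median line,
# whiskers at mean +- 1 sd, and radius histograms truncated at 1.5 um.

#' Box-and-whisker plot of a per-cell variable by treatment
#'
#' Boxes span the 25th-75th percentiles with the median marked; whiskers
#' are mean +- 1 standard deviation; the mean is a thick bar.
#'
#' @param cells cell-summary tibble with a `treatment` column.
#' @param variable per-cell column to plot (tidy-eval).
#' @param log_y use a log10 y axis (default TRUE, as count/volume spans
#'   orders of magnitude across treatments).
#' @return a ggplot object.
#' @export
plot_cell_box <- function(cells, variable, log_y = TRUE) {
  var_q <- rlang::enquo(variable)
  st <- cells |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(box_stats(!!var_q), .groups = "drop")
  p <- ggplot2::ggplot(st, ggplot2::aes(x = .data$treatment)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$whisker_low, ymax = .data$whisker_high),
      width = 0.25
    ) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$p25, ymax = .data$p75),
      fill = "grey85", width = 0.6
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$mean), shape = 95, size = 8
    ) +
    ggplot2::labs(x = NULL, y = rlang::as_label(var_q)) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Histogram of droplet radii by treatment
#'
#' @param droplets droplet tibble (`r_um`, optionally `treatment`).
#' @param truncate_at_um truncate the x axis (default 1.5 um, as in the
#'   experiment's histograms; larger radii are still counted in the data).
#' @param binwidth_um histogram bin width (default 0.05 um).
#' @return a ggplot object.
#' @export
plot_radius_histogram <- function(droplets, truncate_at_um = 1.5,
                                  binwidth_um = 0.05) {
  p <- ggplot2::ggplot(droplets, ggplot2::aes(x = .data$r_um)) +
    ggplot2::geom_histogram(binwidth = binwidth_um, boundary = 0,
                            fill = "steelblue", colour = "grey30",
                            linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = c(0.2, 0.8), linetype = "dashed") +
    ggplot2::coord_cartesian(xlim = c(0, truncate_at_um)) +
    ggplot2::labs(x = "droplet radius (um)", y = "droplets") +
    ggplot2::theme_minimal()
  if (!is.null(droplets$treatment)) {
    p <- p + ggplot2::facet_wrap(~treatment, scales = "free_y")
  }
  p
}

#' Scatter of nucleus-edge distance versus droplet radius
#'
#' @param droplets droplet tibble (`r_um`, `nuc_dist_um`, optionally
#'   `treatment`).
#' @return a ggplot object.
#' @export
plot_distance_scatter <- function(droplets) {
  p <- ggplot2::ggplot(
    droplets,
    ggplot2::aes(x = .data$r_um, y = .data$nuc_dist_um)
  ) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = "droplet radius (um)",
                  y = "distance to nucleus edge (um)") +
    ggplot2::theme_minimal()
  if (!is.null(droplets$treatment)) {
    p <- p + ggplot2::facet_wrap(~treatment)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Display one plane of a rendered field
#'
#' @param object an `ld_field`.
#' @param plane 0-based z index (default: middle plane).
#' @param ... unused.
#' @return a ggplot raster of log-scaled counts.
#' @export
autoplot.ld_field <- function(object, plane = NULL, ...) {
  v <- object$stack$voxels
  if (is.null(plane)) plane <- (dim(v)[3] - 1L) %/% 2L
  m <- v[, , plane + 1L]
  px <- object$stack$pixel_size_um
  df <- expand.grid(
    y = (seq_len(nrow(m)) - 1) * px, x = (seq_len(ncol(m)) - 1) * px
  )
  df$counts <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = log1p(.data$counts))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log(1+counts)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}
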