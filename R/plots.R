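# ggplot2 visualisations for the main result types.

#' Plot a labelled depth profile
#'
#' Per-layer ion totals on a log scale with the region labelling shaded,
#' the standard way sputter depth profiles are displayed.
#'
#' @param profile Labelled profile tibble from [label_regions()] (an
#'   unlabelled one from [extract_profile()] also works).
#' @param peaks Optional subset of peak labels to show.
#' @return A ggplot object.
#' @export
plot_depth_profile <- function(profile, peaks = NULL) {
  if (!is.null(peaks)) profile <- profile[profile$label %in% peaks, ]
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$layer, y = .data$counts + 1,
                                    colour = .data$label))
  if ("region" %in% names(profile)) {
    bands <- profile |>
      dplyr::distinct(.data$layer, .data$region)
    p <- p + ggplot2::geom_tile(
      data = bands,
      ggplot2::aes(x = .data$layer, y = 1, fill = .data$region),
      inherit.aes = FALSE, height = Inf, alpha = 0.15)
  }
  p + ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sputter layer (surface to substrate)",
                  y = "counts per layer + 1", colour = "ion",
                  fill = "region")
}

#' @method autoplot sims_calibration
#' @export
autoplot.sims_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = 2) +
    ggplot2::labs(x = "ciprofloxacin concentration (ug/ml)",
                  y = "(M+H)+ / water cluster intensity ratio",
                  subtitle = sprintf("R^2 = %.4f", object$r_squared))
}

#' @method autoplot mcr_model
#' @export
autoplot.mcr_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$label, y = .data$intensity)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~factor, scales = "free_y") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "peak", y = "normalized factor intensity")
}

#' @method autoplot sims_segmentation
#' @export
autoplot.sims_segmentation <- function(object, ...) {
  ggplot2::ggplot(object$layer_stats,
                  ggplot2::aes(x = .data$layer, y = .data$n_cells)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_live), fill = "firebrick") +
    ggplot2::labs(x = "sputter layer", y = "cells per layer",
                  subtitle = "red: live (K+-retaining) cells")
}

#' Plot one peak channel of one layer as an image
#'
#' @param cube A [sims_cube()].
#' @param peak Peak label.
#' @param layer Layer index (default 1).
#' @return A ggplot raster plot.
#' @export
plot_layer_image <- function(cube, peak, layer = 1) {
  img <- peak_channel(cube, peak)[layer, , ]
  df <- tidyr::expand_grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$counts <- as.vector(t(img))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$counts)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s, layer %d", peak, layer))
}
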