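# ggplot2 displays for the package's result types.

#' @export
autoplot.image_field <- function(object, channel = 1L, ...) {
  img <- field_channel(object, channel)
  df <- tidyr::expand_grid(x = seq_len(nrow(img)), y = seq_len(ncol(img)))
  df$intensity <- img[cbind(df$x, df$y)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "counts")
}

#' @export
autoplot.drift_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), cols = -"frame",
                            names_to = "axis", values_to = "drift_nm")
  df$axis <- sub("^d", "", sub("_nm$", "", df$axis))
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$drift_nm,
                                   colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "drift (nm)", colour = "axis")
}

#' @export
autoplot.ring_measurement <- function(object, ...) {
  ggplot2::ggplot(object$per_angle,
                  ggplot2::aes(factor(.data$angle_deg), .data$diameter_nm)) +
    ggplot2::geom_col(width = 0.6, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_diameter_nm,
                        linetype = "dashed") +
    ggplot2::labs(x = "profile angle (deg)", y = "peak-to-peak diameter (nm)")
}

#' @export
autoplot.cluster_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_axis,
                  ggplot2::aes(.data$axis, .data$width_1e2_nm)) +
    ggplot2::geom_col(width = 0.6, fill = "steelblue") +
    ggplot2::labs(x = "axis", y = "1/e2 width (nm)")
}

#' Scatter display of a localization table
#'
#' @param locs Localization tibble.
#' @param colour Column to colour by (default `channel`).
#' @return A ggplot.
#' @export
plot_locs <- function(locs, colour = "channel") {
  ggplot2::ggplot(as_tibble(locs),
                  ggplot2::aes(.data$x_nm, .data$y_nm,
                               colour = .data[[colour]])) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}
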