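#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a saturation curve
#'
#' Saturation against free calcium on a log axis.
#'
#' @param object A `cam_curve` tibble from [titration_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cam_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$ca_free_molar, y = .data$saturation)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "free calcium (M)", y = "fractional saturation") +
    ggplot2::theme_minimal()
}

#' Plot a titration dataset
#'
#' @param object A `cam_titration` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cam_titration <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$ca_free_molar, y = .data$saturation)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "free calcium (M)", y = "fractional saturation") +
    ggplot2::theme_minimal()
}

#' Plot a Hill-coefficient profile
#'
#' The bell-shaped Hill coefficient along the calcium axis.
#'
#' @param object A `cam_hill_profile` from [hill_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cam_hill_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$ca_free_molar, y = .data$n_H)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "free calcium (M)", y = "Hill coefficient") +
    ggplot2::theme_minimal()
}

#' Plot a score landscape on the (L, c) plane
#'
#' Log10 score as a filled raster with contours; the flat valley of
#' near-optimal parameter pairs appears as the dark band.
#'
#' @param object A `cam_landscape` from [score_landscape()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cam_landscape <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = log10(.data$L), y = log10(.data$c),
                               fill = log10(.data$score))) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(ggplot2::aes(z = log10(.data$score)),
                          colour = "white", linewidth = 0.2, bins = 12) +
    ggplot2::scale_fill_viridis_c(name = "log10 S") +
    ggplot2::labs(x = "log10 L", y = "log10 c") +
    ggplot2::theme_minimal()
}

#' Compare model curves against a titration dataset
#'
#' Convenience overlay: dataset points plus the saturation curve of the
#' mixture attached to it (or a supplied mixture).
#'
#' @param data A `cam_titration` tibble.
#' @param mixture Optional [cam_mixture()] override.
#' @param ca_grid Calcium grid for the model curve.
#' @return A ggplot object.
#' @export
plot_fit_overlay <- function(data, mixture = attr(data, "mixture"),
                             ca_grid = default_ca_grid()) {
  if (is.null(mixture)) stop("no mixture attached to the dataset")
  curve <- titration_curve(mixture, ca_grid)
  autoplot(data) +
    ggplot2::geom_line(data = curve, linewidth = 0.8, colour = "firebrick")
}
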