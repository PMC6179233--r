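#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result types: a raster map
#' for a [grid_surface()], the ROC curve with the four optimized thresholds
#' marked, the mean/sd/CoV panel of an ensemble, the 3x3 panel of
#' combination maps, and a bar chart of zonal areas mirroring the workflow's
#' inside/outside accounting figures.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return a ggplot object.
#' @name reefsdm-plots
NULL

#' @rdname reefsdm-plots
#' @export
autoplot.grid_surface <- function(object, ...) {
  df <- as_tibble(object, drop_na = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' @rdname reefsdm-plots
#' @param thresholds optional [optimize_thresholds()] result to mark on the
#'   curve.
#' @export
autoplot.roc_curve <- function(object, thresholds = NULL, ...) {
  df <- tibble::tibble(fpr = 1 - object$spec, tpr = object$sens)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    pts <- tibble::tibble(fpr = 1 - thresholds$specificity,
                          tpr = thresholds$sensitivity,
                          method = thresholds$method)
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(colour = .data$method), size = 3)
  }
  p
}

#' @rdname reefsdm-plots
#' @export
autoplot.ensemble_surfaces <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("mean", "sd", "cov"), names_to = "layer") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~layer, nrow = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' @rdname reefsdm-plots
#' @export
autoplot.combo_maps <- function(object, ...) {
  df <- purrr::pmap_dfr(
    object[c("probability_level", "precision_level", "mask")],
    function(probability_level, precision_level, mask) {
      d <- as_tibble(mask, drop_na = TRUE)
      d$probability_level <- factor(probability_level, c("low", "moderate", "high"))
      d$precision_level <- factor(precision_level, c("high", "moderate", "low"))
      d
    })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = factor(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey90", `1` = "steelblue"),
                               name = "presence") +
    ggplot2::facet_grid(precision_level ~ probability_level,
                        labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @rdname reefsdm-plots
#' @param report the output of [zonal_report_all()].
#' @export
plot_zonal_areas <- function(report, ...) {
  df <- report |>
    dplyr::mutate(side = ifelse(.data$zone_type == "outside", "outside", "inside")) |>
    dplyr::group_by(.data$probability_level, .data$precision_level, .data$side) |>
    dplyr::summarise(area_km2 = sum(.data$area_m2) / 1e6, .groups = "drop") |>
    dplyr::mutate(
      probability_level = factor(.data$probability_level, c("low", "moderate", "high")),
      precision_level = factor(.data$precision_level, c("high", "moderate", "low"))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$precision_level, y = .data$area_km2,
                                   fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~probability_level, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "precision class", y = "predicted area (km²)") +
    ggplot2::theme_minimal()
}
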