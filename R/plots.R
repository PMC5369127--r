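# ggplot2 methods for the main result types.

#' Plot a raster field
#'
#' @param object A `raster_field` (standardized or composite fields included).
#' @param ... Unused.
#' @return A ggplot object (tile map; nodata cells are blank).
#' @export
autoplot.raster_field <- function(object, ...) {
  df <- tibble::as_tibble(object) %>% filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = attr(object, "units")) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = attr(object, "layer_name"),
      x = "easting (m)", y = "northing (m)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot top-percentile contribution decompositions
#'
#' Side-by-side histogram of per-dimension percentage contributions to the
#' composite above the selected percentile, optionally comparing the two
#' transform methods.
#'
#' @param ... Named `contribution_table`s (e.g. `normal_score = ..., percentile_rank = ...`).
#' @return A ggplot object.
#' @export
plot_contributions <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1)
  if (is.null(names(tabs)) || any(names(tabs) == "")) {
    names(tabs) <- paste0("method_", seq_along(tabs))
  }
  df <- purrr::imap_dfr(tabs, ~ mutate(tibble::as_tibble(.x), method = .y))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$dimension, y = .data$contribution_pct, fill = .data$method
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      y = "contribution above threshold (%)", x = NULL,
      title = "Sub-indicator contributions in the composite upper tail"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a transform curve with its sliding-window slope
#'
#' @param slopes Output of [transform_slope()].
#' @return A ggplot object: score vs raw value, coloured by local slope.
#' @export
plot_transform_curve <- function(slopes) {
  ggplot2::ggplot(slopes, ggplot2::aes(x = .data$raw, y = .data$score, colour = .data$slope)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "local slope") +
    ggplot2::labs(
      x = "raw sub-indicator value", y = "standardized score",
      title = "Transform curve and sliding-window slope"
    ) +
    ggplot2::theme_minimal()
}
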