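# ggplot2 displays for the main result types

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_col
#'   geom_polygon geom_point labs scale_fill_viridis_c scale_fill_brewer
#'   facet_wrap theme_minimal coord_equal
NULL

#' @export
ggplot2::autoplot

#' Heatmap of a parcel similarity matrix
#'
#' @param object A `pitt_simmat` from [similarity_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pitt_simmat <- function(object, ...) {
  d <- expand.grid(i = object$ids, j = object$ids, stringsAsFactors = FALSE)
  d$value <- as.numeric(object$values)
  ggplot(d, aes(x = .data$i, y = .data$j, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(name = object$measure) +
    labs(x = NULL, y = NULL,
         title = sprintf("Pairwise %s of parcel time series", object$measure)) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Per-class scores of an evaluation
#'
#' @param object A `pitt_eval` from [evaluate_classification()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pitt_eval <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_class,
                           c("precision", "recall", "f1"),
                           names_to = "metric")
  ggplot(d, aes(x = .data$class, y = .data$value, fill = .data$metric)) +
    geom_col(position = "dodge") +
    labs(y = NULL, x = NULL,
         title = sprintf("Classification scores (macro-F1 = %.3f)", object$mf1)) +
    theme_minimal()
}

#' Fusion-weight sweep curves
#'
#' @param object A `pitt_weight_sweep` from [weight_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pitt_weight_sweep <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object), -"w", names_to = "score")
  ggplot(d, aes(x = .data$w, y = .data$value, colour = .data$score)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "weight on time-series stream", y = "F1",
         title = sprintf("Fusion weight sweep (best w = %.2f)",
                         attr(object, "best_w"))) +
    theme_minimal()
}

#' Map of a graded parcel mosaic
#'
#' @param parcels Parcel tibble with `geometry` (and optionally `label`,
#'   `branch`).
#' @param colour_by Column used for the fill (default `"label"`).
#' @return A ggplot object.
#' @export
plot_parcels <- function(parcels, colour_by = "label") {
  d <- purrr::map2(parcels$geometry, parcels$parcel_id, function(g, id)
    tibble(parcel_id = id, x = g$outer[, 1], y = g$outer[, 2])) |>
    dplyr::bind_rows() |>
    dplyr::left_join(dplyr::select(parcels, -"geometry"), by = "parcel_id")
  ggplot(d, aes(x = .data$x, y = .data$y, group = .data$parcel_id,
                fill = .data[[colour_by]])) +
    geom_polygon(colour = "grey30", linewidth = 0.1) +
    coord_equal() +
    labs(x = "easting (m)", y = "northing (m)") +
    theme_minimal()
}

#' GAS/TAS against scale level
#'
#' @param tbl Output of [gas_tas_by_scale()].
#' @return A ggplot object.
#' @export
plot_gas_tas <- function(tbl) {
  d <- tidyr::pivot_longer(tbl, c("gas", "tas"), names_to = "statistic")
  ggplot(d, aes(x = factor(.data$scale_level), y = .data$value,
                colour = .data$label, group = interaction(.data$label, .data$statistic))) +
    geom_line() + geom_point() +
    facet_wrap(~ .data$statistic, scales = "free_y") +
    labs(x = "scale level", y = unique(d$measure)) +
    theme_minimal()
}

#' Phenology reference curves
#'
#' @param references A [phenology_reference()].
#' @return A ggplot object.
#' @export
plot_references <- function(references) {
  d <- purrr::imap(references$curves, function(cv, cls)
    purrr::imap(cv, ~ tibble(class = cls, sample = as.character(.y),
                             date = references$dates, value = .x)) |>
      dplyr::bind_rows()) |>
    dplyr::bind_rows()
  ggplot(d, aes(x = .data$date, y = .data$value, colour = .data$class,
                group = interaction(.data$class, .data$sample))) +
    geom_line() +
    labs(x = "day of year", y = "VH backscatter (dB)") +
    theme_minimal()
}
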