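# ggplot2 displays for the main result types. Maps are lat/lon tile
# plots; gradients are richness-vs-latitude curves drawn with latitude on
# the vertical axis, as this field conventionally plots them.

#' @export
autoplot.richness_field <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$lon, .data$lat,
                                 fill = .data$annual)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "richness D") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "longitude", y = "latitude",
                  title = "Annual mean pseudo-species richness",
                  subtitle = if (!is.na(object$zone_id)) object$zone_id) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lbg_profile <- function(object, ...) {
  dplyr::filter(object, !is.na(.data$median_richness)) |>
    ggplot2::ggplot(ggplot2::aes(.data$median_richness, .data$lat)) +
    ggplot2::geom_path() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "median richness across longitudes",
                  y = "latitude",
                  title = "Latitudinal biodiversity gradient") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lbg_matrix <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$bin_lo + (.data$bin_hi - .data$bin_lo) / 2,
                               .data$lat, fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% of longitudes") +
    ggplot2::labs(x = "standardized richness", y = "latitude",
                  title = "Latitudinal gradient across longitudes") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.climatology_grid <- function(object, month = NULL, ...) {
  tab <- tidy(object)
  if (!is.null(month)) {
    tab <- dplyr::filter(tab, .data$month == !!month)
  } else {
    tab <- tab |>
      dplyr::group_by(.data$lat, .data$lon) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  ggplot2::ggplot(tab, ggplot2::aes(.data$lon, .data$lat,
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = object$units) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "longitude", y = "latitude",
                  title = paste0(object$variable,
                                 if (is.null(month)) " (annual mean)" else
                                   paste0(" (month ", month, ")"))) +
    ggplot2::theme_minimal()
}

#' Map of allopatric range components for one niche
#'
#' @param labeling A [label_components()] result.
#' @param lat,lon Optional coordinates for axes.
#' @return A ggplot object; each component in its own colour.
#' @export
plot_range_components <- function(labeling, lat = NULL, lon = NULL) {
  stopifnot(inherits(labeling, "range_labeling"))
  m <- labeling$labels
  lat <- lat %||% seq_len(nrow(m))
  lon <- lon %||% seq_len(ncol(m))
  tidyr::expand_grid(lon = lon, lat = lat) |>
    dplyr::mutate(component = as.vector(m)) |>
    dplyr::filter(.data$component > 0) |>
    ggplot2::ggplot(ggplot2::aes(.data$lon, .data$lat,
                                 fill = factor(.data$component))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "species") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "longitude", y = "latitude",
                  title = "Allopatric range components") +
    ggplot2::theme_minimal()
}
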