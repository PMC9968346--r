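# ggplot2 visualisations of the core result types.

#' @importFrom ggplot2 ggplot aes geom_tile geom_point geom_line geom_col
#'   scale_fill_viridis_c facet_wrap labs theme_minimal geom_hex
NULL

#' Plot a landscape variable as a map
#'
#' @param object A `sieve_landscape`.
#' @param var Variable to map (default `elevation`).
#' @param ... Ignored.
#' @export
autoplot.sieve_landscape <- function(object, var = "elevation", ...) {
  d <- as_tibble(object)
  d$value <- ifelse(d$land, d[[var]], NA_real_)
  ggplot(d, aes(x = .data$lon, y = .data$lat, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(na.value = "grey90") +
    labs(fill = var, x = "longitude", y = "latitude") +
    theme_minimal()
}

#' Plot a TDOA origin-score surface
#'
#' @param object A `sieve_origin`.
#' @param ... Ignored.
#' @export
autoplot.sieve_origin <- function(object, ...) {
  b <- attr(object, "best")
  ggplot(as_tibble(object), aes(x = .data$lon, y = .data$lat)) +
    geom_tile(aes(fill = .data$r2)) +
    geom_point(data = b, colour = "red", shape = 4, size = 3) +
    scale_fill_viridis_c() +
    labs(fill = expression(R^2), x = "longitude", y = "latitude",
         title = "TDOA expansion-origin surface") +
    theme_minimal()
}

#' Plot turnover (cumulative importance) functions
#'
#' @param object A `sieve_turnover`.
#' @param ... Ignored.
#' @export
autoplot.sieve_turnover <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$knot, y = .data$cumimp)) +
    geom_line() +
    facet_wrap(~predictor, scales = "free_x") +
    labs(x = "predictor value", y = "cumulative importance") +
    theme_minimal()
}

#' Plot offset validation goodness-of-fit
#'
#' @param object A `sieve_validation`.
#' @param ... Ignored.
#' @export
autoplot.sieve_validation <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), !.data$flagged)
  ggplot(d, aes(x = stats::reorder(.data$statistic, .data$adj_r_squared),
                y = .data$adj_r_squared)) +
    geom_col() +
    ggplot2::coord_flip() +
    labs(x = NULL, y = expression(adjusted ~ R^2)) +
    theme_minimal()
}

#' Map the glacial genomic offset of populations
#'
#' @param offsets A `sieve_offset`.
#' @param pop_table Tibble with `id`, `lon`, `lat`.
#' @export
plot_offset_map <- function(offsets, pop_table) {
  d <- dplyr::left_join(as_tibble(offsets), pop_table, by = "id")
  ggplot(d, aes(x = .data$lon, y = .data$lat, colour = .data$offset)) +
    geom_point(size = 3) +
    scale_fill_viridis_c(aesthetics = "colour") +
    labs(x = "longitude", y = "latitude", colour = "glacial\ngenomic\noffset") +
    theme_minimal()
}
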