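# ggplot2 graphics: dartboard/region maps, kernel traces, RAD summaries.

# polygon vertices approximating one dart segment
.segment_polygon <- function(inner, outer, start, end, n_arc = 24) {
  if (end <= start) end <- end + 360
  ang <- seq(start, end, length.out = n_arc) * pi / 180
  tibble::tibble(
    x = c(outer * cos(ang), inner * cos(rev(ang))),
    y = c(outer * sin(ang), inner * sin(rev(ang)))
  )
}

#' Plot the dartboard geometry or a region map
#'
#' Draws the 60 dart segments in screen coordinates; if `segments` carries a
#' `region_label` column (a region map), segments are filled by region.
#'
#' @param segments A [build_dartboard()] tibble or [assign_regions()] map.
#' @return A ggplot object.
#' @export
plot_dartboard <- function(segments) {
  polys <- purrr::pmap(
    list(segments$segment_id, segments$inner_ecc, segments$outer_ecc,
         segments$start_angle, segments$end_angle),
    function(id, inner, outer, start, end) {
      p <- .segment_polygon(inner, outer, start, end)
      p$segment_id <- id
      p
    }) |> dplyr::bind_rows()
  if ("region_label" %in% names(segments)) {
    polys$region_label <- segments$region_label[match(polys$segment_id,
                                                      segments$segment_id)]
    aes <- ggplot2::aes(x = .data$x, y = .data$y,
                        group = .data$segment_id, fill = .data$region_label)
  } else {
    aes <- ggplot2::aes(x = .data$x, y = .data$y, group = .data$segment_id)
  }
  ggplot2::ggplot(polys, aes) +
    ggplot2::geom_polygon(colour = "white", linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "eccentricity (deg)", y = "eccentricity (deg)",
                  fill = "region") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.region_map <- function(object, ...) plot_dartboard(object)

#' Plot kernel traces
#'
#' @param kernels A kernel-set matrix.
#' @param segment_ids Segments to show (default: first 6).
#' @return A ggplot object.
#' @export
plot_kernels <- function(kernels, segment_ids = 0:5) {
  df <- kernel_tidy(kernels) |>
    dplyr::filter(.data$segment_id %in% segment_ids)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$amplitude)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~segment_id, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time from stimulus onset (ms)",
                  y = "response density (nV/deg²)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kernel_set <- function(object, ...) plot_kernels(object, ...)

#' Plot group RAD means by region
#'
#' Mean and one-SD error bars per region and group for one topography, in
#' canonical region order -- the layout of the study's summary figures.
#'
#' @param rad_table A [build_rad_table()] tibble.
#' @param scheme Topography to plot.
#' @return A ggplot object.
#' @export
plot_rad_profile <- function(rad_table, scheme = c("rings", "sectors", "etdrs")) {
  scheme <- match.arg(scheme)
  summ <- .rad_to_summaries(rad_table, scheme) |>
    dplyr::arrange(.data$region_order)
  summ$region_label <- factor(summ$region_label,
                              levels = .canonical_regions[[scheme]])
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$region_label, y = .data$mean,
                                     colour = .data$group, group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::labs(x = "region", y = "mean RAD (nV/deg²)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ecc_fit <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linetype = 2) +
    ggplot2::labs(x = "region index", y = "mean RAD (nV/deg²)",
                  subtitle = sprintf("%s fit, r² = %.2f", object$kind,
                                     object$r_squared)) +
    ggplot2::theme_minimal()
}
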