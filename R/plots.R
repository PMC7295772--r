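#' Plot an oocyte size frequency distribution
#'
#' Histogram of oocyte diameters with the smoothed density overlaid (when
#' present), the classification-window limits as solid vertical lines, and
#' the approximate onset of final oocyte maturation (875 um) as a dashed
#' line (annotation only; never used in classification).
#'
#' @param object an \code{\link{build_osfd}} object.
#' @param bounds a \code{\link{class_bounds}} for the window annotations.
#' @param fom_onset_um dashed annotation line (um); NA to omit.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.osfd <- function(object, bounds = class_bounds(),
                          fom_onset_um = 875, ...) {
  h <- object$histogram
  w <- object$bin_width_um
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_start_um + w / 2,
                                       y = .data$count)) +
    ggplot2::geom_col(width = w, fill = "grey65", colour = "grey30",
                      linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = c(bounds$dev_min_um, bounds$dev_max_um),
                        linewidth = 0.4) +
    ggplot2::labs(x = "Oocyte diameter (µm)", y = "Count",
                  title = object$fish_id) +
    ggplot2::theme_minimal()
  if (!is.na(fom_onset_um)) {
    p <- p + ggplot2::geom_vline(xintercept = fom_onset_um, linetype = "dashed")
  }
  if (!is.null(object$density)) {
    dens <- object$density
    scale <- length(object$diameters_um) * w
    p <- p + ggplot2::geom_line(
      data = dens,
      ggplot2::aes(x = .data$diameter_um, y = .data$density * scale),
      colour = "firebrick", linewidth = 0.6
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Smoothed OSFD profile plot for a whole study
#'
#' One smoothed OSFD curve per fish, facetted in reading order by ORC and
#' then by maximum oocyte diameter, emulating a ridge-style study overview.
#'
#' @param oocytes long tibble with \code{fish_id}, \code{diameter_um}.
#' @param classification per-fish tibble with \code{fish_id}, \code{orc}.
#' @param bounds a \code{\link{class_bounds}}.
#' @return A ggplot object.
#' @export
plot_osfd_profiles <- function(oocytes, classification,
                               bounds = class_bounds()) {
  df <- dplyr::inner_join(oocytes, classification[, c("fish_id", "orc")],
                          by = "fish_id")
  ord <- df |>
    dplyr::group_by(.data$fish_id, .data$orc) |>
    dplyr::summarise(max_d = max(.data$diameter_um), .groups = "drop") |>
    dplyr::arrange(.data$orc, .data$max_d)
  df$fish_id <- factor(df$fish_id, levels = ord$fish_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diameter_um,
                                   colour = factor(.data$orc))) +
    ggplot2::geom_density(bw = 25) +
    ggplot2::facet_wrap(~fish_id, scales = "free_y") +
    ggplot2::geom_vline(xintercept = c(bounds$dev_min_um, bounds$dev_max_um),
                        linewidth = 0.3) +
    ggplot2::labs(x = "Oocyte diameter (µm)", y = "Density",
                  colour = "ORC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Tukey-style boxplots of a metric across ORCs
#'
#' @param data tibble with the metric and an \code{orc} column.
#' @param metric column name (string) of the metric.
#' @param comparison optional \code{\link{compare_orc_groups}} result whose
#'   significance letters are drawn above each box.
#' @return A ggplot object.
#' @export
plot_orc_boxplot <- function(data, metric, comparison = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = factor(.data$orc),
                                          y = .data[[metric]])) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "Oocyte ratio category (ORC)", y = metric) +
    ggplot2::theme_minimal()
  if (!is.null(comparison) && !is.null(comparison$pairwise)) {
    lets <- comparison$pairwise$letters
    ann <- data |>
      dplyr::group_by(.data$orc) |>
      dplyr::summarise(y = max(.data[[metric]]), .groups = "drop") |>
      dplyr::mutate(label = unname(lets[as.character(.data$orc)]))
    p <- p + ggplot2::geom_text(
      data = ann,
      ggplot2::aes(x = factor(.data$orc), y = .data$y, label = .data$label),
      vjust = -0.5
    )
  }
  p
}
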