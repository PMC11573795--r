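#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an IRL test
#'
#' Observed versus expected mitochondrial profile counts per compartment,
#' annotated with the IRL values.
#'
#' @param object An `irl_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.irl_test <- function(object, ...) {
  tab <- object$table |>
    tidyr::pivot_longer(c("n_0", "n_e"), names_to = "kind",
                        values_to = "count") |>
    dplyr::mutate(kind = dplyr::recode(.data$kind, n_0 = "observed",
                                       n_e = "expected"))
  ggplot2::ggplot(tab, ggplot2::aes(.data$compartment, .data$count,
                                    fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = object$table,
      ggplot2::aes(.data$compartment, pmax(.data$n_0, .data$n_e),
                   label = sprintf("IRL %.2f", .data$irl)),
      inherit.aes = FALSE, vjust = -0.4
    ) +
    ggplot2::labs(y = "mitochondrial profiles", x = NULL, fill = NULL,
                  title = sprintf("X-squared = %.2f (df %d)",
                                  object$statistic, object$df)) +
    ggplot2::theme_minimal()
}

#' Plot a colocalization result
#'
#' The Van Steensel cross-correlation curve with the peak shift marked.
#'
#' @param object A `coloc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coloc_result <- function(object, ...) {
  ggplot2::ggplot(object$ccf, ggplot2::aes(.data$shift, .data$ccf)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$ccf_peak_shift,
                        linetype = "dashed") +
    ggplot2::labs(
      x = "shift (px)", y = "cross-correlation",
      title = sprintf("%s (Pearson %.2f, peak at %d px)",
                      object$case, object$pc_global,
                      object$ccf_peak_shift)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic section
#'
#' Label raster with mitochondrial profile centroids overlaid.
#'
#' @param section A `synthetic_section`.
#' @param max_px Downsampling cap on the longer raster edge for display.
#' @return A ggplot.
#' @export
plot_section <- function(section, max_px = 512L) {
  lab <- section$labels
  step <- max(1L, ceiling(max(dim(lab)) / max_px))
  rows <- seq(1L, nrow(lab), by = step)
  cols <- seq(1L, ncol(lab), by = step)
  s <- section$pixel_size_um
  df <- tidyr::expand_grid(row = rows, col = cols)
  df$compartment <- names(COMPARTMENTS)[
    match(lab[cbind(df$row, df$col)], COMPARTMENTS)]
  ggplot2::ggplot(df, ggplot2::aes((.data$col - 0.5) * s,
                                   (.data$row - 0.5) * s,
                                   fill = .data$compartment)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(
      data = section$profiles,
      ggplot2::aes(.data$x_um, .data$y_um), inherit.aes = FALSE,
      size = 0.3, colour = "black"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = NULL) +
    ggplot2::theme_minimal()
}
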