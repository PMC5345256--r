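#' Plot a peak chart as an electropherogram
#'
#' @param object A `peak_chart` tibble (or several row-bound charts, which
#'   are faceted by sample).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot peak_chart
#' @export
autoplot.peak_chart <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$size, y = .data$height)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$size, yend = 0),
                          linewidth = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample), ncol = 1) +
    ggplot2::labs(x = "fragment size (nt)", y = "intensity (RFU)",
                  title = sprintf("selective pair %s / %s",
                                  object$sel_primary[1], object$sel_secondary[1])) +
    ggplot2::theme_minimal()
}

#' Plot a Hill calibration with its points
#'
#' @param object A [fit_hill()] object.
#' @param ... Unused.
#' @return A ggplot of percent methylation against signal ratio.
#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, ...) {
  rng <- range(object$points$sr)
  grid <- tibble(sr = seq(max(rng[1] * 0.5, 0), rng[2] * 1.1, length.out = 200))
  grid$percent <- hill_percent(object, grid$sr)
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$sr, y = .data$percent)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(x = "signal ratio (sample / SssI reference)",
                  y = "percent methylation (MSRE-PCR)",
                  title = "Hill calibration") +
    ggplot2::theme_minimal()
}

#' PCA score plot of a methylation ordination
#'
#' @param ord A [zscore_pca_cluster()] result.
#' @param axes Two principal-component indices to display.
#' @return A ggplot of sample scores coloured by group.
#' @export
plot_meth_pca <- function(ord, axes = c(1, 2)) {
  stopifnot(inherits(ord, "meth_ordination"), length(axes) == 2)
  cols <- paste0("PC", axes)
  lab <- sprintf("%s (%.1f%%)", cols, 100 * ord$var_explained[axes])
  ggplot2::ggplot(ord$scores,
                  ggplot2::aes(x = .data[[cols[1]]], y = .data[[cols[2]]],
                               colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = lab[1], y = lab[2], colour = "group",
                  title = "PCA of z-scored methylation profiles") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
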