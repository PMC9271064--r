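#' Plot a fitted proliferation-rate map on the mesh
#'
#' Draws the tumor elements colored by their regional proliferation rate
#' (blue = net cell death, yellow/red = net proliferation), over the meshed
#' host-tissue outline.
#'
#' @param fit a `prolif_fit`.
#' @param mesh the `tri_mesh` the fit was computed on.
#' @return a ggplot object.
#' @export
plot_proliferation_map <- function(fit, mesh) {
  part <- fit$partition
  k_elem <- fit$k_regions[part$region_of_element]
  el <- part$elements
  tri <- mesh$triangles[el, , drop = FALSE]
  df <- tibble::tibble(
    x = as.vector(t(matrix(mesh$nodes[tri, 1], nrow(tri), 3))),
    y = as.vector(t(matrix(mesh$nodes[tri, 2], nrow(tri), 3))),
    elem = rep(seq_len(nrow(tri)), each = 3),
    k = rep(k_elem, each = 3))
  lim <- max(abs(k_elem), 0.01)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$elem,
                                   fill = .data$k)) +
    ggplot2::geom_polygon(color = NA) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "grey95",
                                  high = "#B2182B", limits = c(-lim, lim),
                                  name = expression(k ~ (day^-1))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("Proliferation map (%s)", fit$pair_label)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_proliferation_map
#' @param object a `prolif_fit`.
#' @param ... passed on (must include `mesh`).
#' @method autoplot prolif_fit
#' @export
autoplot.prolif_fit <- function(object, mesh, ...) {
  plot_proliferation_map(object, mesh)
}

#' Plot a proliferation-rate histogram
#'
#' Area-weighted histogram of the regional proliferation rates with the
#' summary mean and median marked.
#'
#' @param object a `hist_summary`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot hist_summary
#' @export
autoplot.hist_summary <- function(object, ...) {
  df <- tidy.hist_summary(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_mid, .data$weight)) +
    ggplot2::geom_col(width = object$bin_width * 0.95, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$mean, color = "#B2182B",
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = object$median, color = "#2166AC",
                        linetype = 3) +
    ggplot2::labs(x = expression(k ~ (day^-1)), y = expression(area ~ (mm^2)),
                  title = "Proliferation-rate histogram") +
    ggplot2::theme_minimal()
}

#' Plot an image-grid map (ADC or cellularity)
#'
#' @param object an `adc_map` or `cellularity_map`.
#' @param spacing mm per pixel (default 1 mm isotropic).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot adc_map
#' @export
autoplot.adc_map <- function(object, spacing = c(1, 1), ...) {
  plot_image_grid(object$values, spacing, "ADC (mm^2/s)")
}

#' @rdname autoplot.adc_map
#' @method autoplot cellularity_map
#' @export
autoplot.cellularity_map <- function(object, spacing = c(1, 1), ...) {
  plot_image_grid(object$values, spacing, "N (cells/voxel)")
}

plot_image_grid <- function(values, spacing, fill_name) {
  df <- tidyr::expand_grid(i = seq_len(nrow(values)), j = seq_len(ncol(values)))
  df$x <- (df$i - 1) * spacing[1]
  df$y <- (df$j - 1) * spacing[2]
  df$v <- values[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = fill_name, na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Scatter plots of histogram metrics against RCB outcome
#'
#' One panel per metric and time-point pair, with the least-squares line —
#' the cohort-level view from which the correlation tables are computed.
#'
#' @param result a `pipeline_result` (or a cohort table tibble).
#' @param metrics metrics to show (default mean, median, p75).
#' @param outcome `"total"` or `"in_breast"`.
#' @return a ggplot object.
#' @export
plot_cohort_correlations <- function(result,
                                     metrics = c("mean", "median", "p75"),
                                     outcome = c("total", "in_breast")) {
  outcome <- match.arg(outcome)
  tab <- if (inherits(result, "pipeline_result")) result$cohort_table else result
  tab <- dplyr::filter(tab, .data$metric %in% metrics)
  tab$rcb <- if (outcome == "total") tab$rcb_total else tab$rcb_in_breast
  ggplot2::ggplot(tab, ggplot2::aes(.data$value, .data$rcb)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "grey60", linewidth = 0.5) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_grid(pair_label ~ metric, scales = "free_x") +
    ggplot2::labs(x = "histogram metric (1/day)",
                  y = if (outcome == "total") "RCB" else "in-breast RCB") +
    ggplot2::theme_bw()
}
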