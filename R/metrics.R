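# Weighted type-7 quantile: positions p_i = (c_i - w_i) / (W - w_i) with
# c_i the cumulative weight; reduces exactly to R's default type-7 quantile
# when all weights are equal. Positions are monotonised defensively for
# strongly unequal weights.
weighted_quantile7 <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  W <- sum(w)
  if (length(x) == 1L) return(rep(x, length(probs)))
  cw <- cumsum(w)
  pos <- (cw - w) / (W - w)
  pos <- cummax(pos)
  pos[length(pos)] <- 1
  stats::approx(pos, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Histogram summary of a regional proliferation map
#'
#' Expands the fitted regional rates to element level, weights each element by
#' its area, and summarizes the resulting spatial distribution: area-weighted
#' mean, median, 25th/75th percentile (linear-interpolation quantiles on the
#' weighted empirical distribution, not on binned midpoints), IQR and standard
#' deviation. Histogram bins of width `bin_width` are returned for plotting.
#'
#' @param fit a `prolif_fit` (or a numeric vector of per-region rates).
#' @param partition the `region_partition` used in the fit (defaults to the
#'   one stored in the fit).
#' @param mesh the `tri_mesh` the partition lives on; supplies element areas.
#' @param bin_width histogram bin width in 1/day (default 0.1).
#' @return object of class `hist_summary`: `mean`, `median`, `iqr`, `std`,
#'   `p25`, `p75` (1/day), `bin_width`, `bin_edges`, `bin_counts`
#'   (area-weighted), and the element-level values/weights.
#' @export
proliferation_histogram <- function(fit, partition = NULL, mesh = NULL,
                                    bin_width = 0.1) {
  k_regions <- if (inherits(fit, "prolif_fit")) fit$k_regions else fit
  if (is.null(partition) && inherits(fit, "prolif_fit")) partition <- fit$partition
  if (is.null(partition) || length(partition$elements) == 0L)
    stop("empty partition")
  k_elem <- k_regions[partition$region_of_element]
  w <- if (!is.null(mesh)) mesh$areas[partition$elements]
       else rep(1, length(k_elem))
  W <- sum(w)
  m <- sum(w * k_elem) / W
  sd_w <- sqrt(sum(w * (k_elem - m)^2) / W)
  q <- weighted_quantile7(k_elem, w, c(0.25, 0.5, 0.75))
  lo <- floor(min(k_elem) / bin_width) * bin_width
  hi <- ceiling(max(k_elem) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi + 1e-12, by = bin_width)
  bin <- pmin(findInterval(k_elem, edges, rightmost.closed = TRUE),
              length(edges) - 1L)
  counts <- as.vector(tapply(w, factor(bin, levels = seq_len(length(edges) - 1L)),
                             sum, default = 0))
  structure(list(mean = m, median = q[2], iqr = q[3] - q[1], std = sd_w,
                 p25 = q[1], p75 = q[3], bin_width = bin_width,
                 bin_edges = edges, bin_counts = counts,
                 values = k_elem, weights = w),
            class = "hist_summary")
}

#' @export
print.hist_summary <- function(x, ...) {
  cat(sprintf(
    "<hist_summary> mean %.4f, median %.4f, p25 %.4f, p75 %.4f, IQR %.4f, sd %.4f /day\n",
    x$mean, x$median, x$p25, x$p75, x$iqr, x$std))
  invisible(x)
}

#' Tumor longest dimension
#'
#' Maximum pairwise Euclidean distance between ROI voxel centers (in-plane).
#'
#' @param roi logical matrix.
#' @param spacing mm per pixel.
#' @return mm (0 for a single voxel).
#' @export
longest_dimension <- function(roi, spacing) {
  idx <- which(roi, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty ROI")
  if (nrow(idx) == 1L) return(0)
  pts <- cbind((idx[, 1] - 1) * spacing[1], (idx[, 2] - 1) * spacing[2])
  hull <- grDevices::chull(pts)
  max(stats::dist(pts[hull, , drop = FALSE]))
}

#' Mean tumor ADC
#'
#' Arithmetic mean of the valid ADC values inside the ROI.
#'
#' @param adc_map an `adc_map`.
#' @param roi logical matrix.
#' @return mm^2/s.
#' @export
mean_tumor_adc <- function(adc_map, roi) {
  inside <- roi & adc_map$valid_mask
  if (!any(inside)) stop("no valid ADC voxels inside the ROI")
  mean(adc_map$values[inside])
}

#' Functional tumor volume
#'
#' Voxel count of the enhancement-defined ROI times the voxel volume.
#'
#' @param roi logical matrix (from the 80 percent enhancement rule).
#' @param spacing mm per pixel.
#' @param slice_thickness mm.
#' @return mm^3 (0 for an empty ROI).
#' @export
functional_tumor_volume <- function(roi, spacing, slice_thickness) {
  sum(roi) * spacing[1] * spacing[2] * slice_thickness
}

#' Change in a metric between two time points
#'
#' @param value_a,value_b metric values at the earlier and later time point.
#' @param mode `"percent"` (default): `(b - a)/a * 100`; `"absolute"`:
#'   `b - a`. Shrinkage is negative in both modes.
#' @return the change.
#' @export
delta_metric <- function(value_a, value_b, mode = c("percent", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(is.finite(value_a), is.finite(value_b))
  if (mode == "absolute") return(value_b - value_a)
  if (value_a == 0) stop("percent change undefined for a zero baseline value")
  (value_b - value_a) / value_a * 100
}
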