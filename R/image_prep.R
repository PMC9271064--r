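#' Apparent diffusion coefficient map from DW-MRI signals
#'
#' Per voxel, averages `ln(S0/S_i)/b` over the three orthogonal diffusion
#' encoding directions at a single diffusion weighting `b_select`
#' (`method = "single_b"`, the default), or fits a log-linear least-squares
#' decay over all b-values per direction and averages the three slopes
#' (`method = "multi_b"`).
#'
#' @param dw_signals 4D array `[nx, ny, n_b, 3]`: signal images per b-value
#'   and diffusion direction.
#' @param b_values numeric, s/mm^2, matching the third dimension; must
#'   include 0.
#' @param b_select the single b-value used by the default method (s/mm^2),
#'   default 800.
#' @param method `"single_b"` or `"multi_b"`.
#' @return object of class `adc_map`: `values` (mm^2/s, `NaN` where invalid),
#'   `valid_mask`, and the fitting settings. Voxels with non-positive signal
#'   or diffusion signal exceeding S0 are flagged invalid.
#' @export
compute_adc <- function(dw_signals, b_values, b_select = 800,
                        method = c("single_b", "multi_b")) {
  method <- match.arg(method)
  stopifnot(length(dim(dw_signals)) == 4, dim(dw_signals)[3] == length(b_values))
  if (dim(dw_signals)[4] < 3)
    stop("three orthogonal diffusion directions are required")
  if (!any(b_values == 0)) stop("a b = 0 image is required")
  nx <- dim(dw_signals)[1]; ny <- dim(dw_signals)[2]
  S0 <- apply(dw_signals[, , which(b_values == 0)[1], , drop = FALSE],
              c(1, 2), mean)
  if (method == "single_b") {
    if (!b_select %in% b_values || b_select == 0)
      stop("b_select must be one of the nonzero acquired b-values")
    bi <- which(b_values == b_select)[1]
    adc_dir <- array(NA_real_, c(nx, ny, 3))
    valid <- S0 > 0
    for (d in 1:3) {
      Si <- dw_signals[, , bi, d]
      valid <- valid & Si > 0 & Si <= S0
      adc_dir[, , d] <- log(pmax(S0, .Machine$double.xmin) /
                            pmax(Si, .Machine$double.xmin)) / b_select
    }
    values <- apply(adc_dir, c(1, 2), mean)
  } else {
    nb <- length(b_values)
    bbar <- mean(b_values)
    sxx <- sum((b_values - bbar)^2)
    values <- matrix(0, nx, ny)
    valid <- matrix(TRUE, nx, ny)
    for (d in 1:3) {
      logs <- array(NA_real_, c(nx, ny, nb))
      for (k in seq_len(nb)) {
        S <- dw_signals[, , k, d]
        valid <- valid & S > 0
        logs[, , k] <- log(pmax(S, .Machine$double.xmin))
      }
      lbar <- apply(logs, c(1, 2), mean)
      slope <- matrix(0, nx, ny)
      for (k in seq_len(nb))
        slope <- slope + (b_values[k] - bbar) * (logs[, , k] - lbar)
      values <- values + (-slope / sxx) / 3
    }
    valid <- valid & values >= 0
  }
  values[!valid] <- NaN
  if (!any(valid)) stop("ADC fit produced no valid voxels")
  structure(list(values = values, valid_mask = valid,
                 b_select = b_select, method = method),
            class = "adc_map")
}

#' @export
print.adc_map <- function(x, ...) {
  cat(sprintf("<adc_map> %d x %d, %d valid voxels, ADC range [%.3g, %.3g] mm^2/s\n",
              nrow(x$values), ncol(x$values), sum(x$valid_mask),
              min(x$values[x$valid_mask]), max(x$values[x$valid_mask])))
  invisible(x)
}

# 8-connected component labeling by BFS; returns integer label matrix (0 = bg)
label_components_8 <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  off <- expand.grid(di = -1:1, dj = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0), ]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      i <- (v - 1L) %% nx + 1L; j <- (v - 1L) %/% nx + 1L
      ni <- i + off$di; nj <- j + off$dj
      keep <- ni >= 1 & ni <= nx & nj >= 1 & nj <= ny
      nb <- (nj[keep] - 1L) * nx + ni[keep]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Tumor ROI from contrast enhancement
#'
#' Refines a coarse seed segmentation by keeping voxels whose post-contrast
#' signal is at least `1 + threshold` times the pre-contrast signal
#' (80 percent enhancement by default, inclusive), then keeps the largest
#' 8-connected component.
#'
#' @param dce_pre,dce_post pre/post-contrast images (same grid).
#' @param seed_mask logical matrix, coarse manual/synthetic segmentation.
#' @param threshold fractional enhancement threshold (default 0.8).
#' @return logical matrix, the refined ROI.
#' @export
segment_tumor <- function(dce_pre, dce_post, seed_mask, threshold = 0.8) {
  stopifnot(all(dim(dce_pre) == dim(dce_post)),
            all(dim(dce_pre) == dim(seed_mask)))
  enhanced <- dce_post >= (1 + threshold) * dce_pre
  mask <- seed_mask & enhanced
  if (!any(mask))
    stop(structure(class = c("prolifmap_empty_roi", "error", "condition"),
                   list(message = "enhancement segmentation is empty; review the seed mask or threshold",
                        call = sys.call(-1))))
  lab <- label_components_8(mask)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Cellular carrying capacity of an imaging voxel
#'
#' The maximum number of tumor cells per voxel: voxel volume times the sphere
#' packing density, divided by the nominal (spherical) tumor cell volume.
#'
#' @param pixel_spacing numeric length-2, mm.
#' @param slice_thickness mm.
#' @param cell_radius nominal tumor cell radius in micrometers (default 10).
#' @param packing_density sphere packing density (default 0.7405, close
#'   packing).
#' @return list with `theta` (cells/voxel), `cell_volume_um3` and
#'   `voxel_volume_mm3`.
#' @export
carrying_capacity <- function(pixel_spacing, slice_thickness,
                              cell_radius = 10, packing_density = 0.7405) {
  stopifnot(all(pixel_spacing > 0), slice_thickness > 0,
            cell_radius > 0, packing_density > 0)
  voxel_mm3 <- pixel_spacing[1] * pixel_spacing[2] * slice_thickness
  cell_um3 <- 4 / 3 * pi * cell_radius^3
  theta <- packing_density * (voxel_mm3 * 1e9) / cell_um3
  list(theta = theta, cell_volume_um3 = cell_um3, voxel_volume_mm3 = voxel_mm3)
}

#' Tumor cellularity from an ADC map
#'
#' Linearly maps ADC to cell count: `N = theta * (ADC_w - ADC) / (ADC_w -
#' ADC_min)`, where `ADC_w` is the free-water value at 37 C and `ADC_min` the
#' minimum ADC within the tumor (the densest voxel). Values are clamped to
#' `[0, theta]` and defined only inside the ROI.
#'
#' @param adc_map an `adc_map`.
#' @param roi logical matrix, tumor ROI.
#' @param theta carrying capacity, cells/voxel.
#' @param adc_w free-water ADC, mm^2/s (default 3e-3).
#' @param adc_min minimum tumor ADC; computed from this map's ROI when `NULL`.
#'   Pass a patient-level minimum for consistency across time points.
#' @return object of class `cellularity_map`: `values` (cells/voxel, `NA`
#'   outside the ROI), `theta`, `adc_w`, `adc_min`.
#' @export
cellularity_from_adc <- function(adc_map, roi, theta, adc_w = 3e-3,
                                 adc_min = NULL) {
  stopifnot(inherits(adc_map, "adc_map"), any(roi), adc_w > 0)
  inside <- roi & adc_map$valid_mask
  if (!any(inside)) stop("no valid ADC voxels inside the ROI")
  if (is.null(adc_min)) adc_min <- min(adc_map$values[inside])
  if (adc_min >= adc_w)
    stop("ADC_min >= ADC_w: degenerate cellularity denominator")
  values <- theta * (adc_w - adc_map$values) / (adc_w - adc_min)
  values <- pmin(pmax(values, 0), theta)
  values[!inside] <- NA_real_
  structure(list(values = values, theta = theta, adc_w = adc_w,
                 adc_min = adc_min, roi = inside),
            class = "cellularity_map")
}

#' @export
print.cellularity_map <- function(x, ...) {
  cat(sprintf("<cellularity_map> %d ROI voxels, N in [%.3g, %.3g] of theta = %.4g cells/voxel\n",
              sum(x$roi), min(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE), x$theta))
  invisible(x)
}

#' Extract the central tumor slice from a volume
#'
#' Selects the middle slice of the baseline ROI extent (upper median for even
#' counts) and applies the same index to every time point. 2D input passes
#' through unchanged.
#'
#' @param volume_stack list of 3D arrays (one per time point), or a single 3D
#'   array, or 2D matrices (pass-through).
#' @param roi_stack matching ROI volumes; the first entry is the baseline.
#' @return list with `slice_index` and `images` (list of 2D matrices).
#' @export
extract_central_slice <- function(volume_stack, roi_stack) {
  if (!is.list(volume_stack)) volume_stack <- list(volume_stack)
  if (!is.list(roi_stack)) roi_stack <- list(roi_stack)
  if (length(dim(volume_stack[[1]])) == 2L)
    return(list(slice_index = 1L, images = volume_stack))
  base_roi <- roi_stack[[1]]
  slices <- which(apply(base_roi, 3, any))
  if (!length(slices)) stop("baseline ROI is empty")
  sl <- slices[ceiling(length(slices) / 2)]
  list(slice_index = sl,
       images = lapply(volume_stack, function(v) v[, , sl]))
}
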