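#' Synthetic breast phantom with ground-truth biophysics
#'
#' Builds a 2D central-slice phantom: an elliptical breast domain, a disc/
#' ellipse tumor with a smooth initial cell-fraction profile, a regional
#' ground-truth proliferation-rate map, and the acquisition schedule. This is
#' the fixture standing in for patient MRI; everything downstream (meshing,
#' forward simulation, rendering, inversion) runs on it unchanged.
#'
#' @param grid_shape integer length-2 (default `c(64, 64)`).
#' @param pixel_spacing mm per pixel (default `c(1, 1)`).
#' @param tumor_spec list: `center_mm` (default grid center), `radius_mm`
#'   (default 10), optional `aspect` (y/x semi-axis ratio, default 1), and
#'   `profile`: `"taper"` (default; cell fraction falls smoothly to 0 at the
#'   rim) or `"plateau"` (uniform fraction with a sharp rim, as in a solidly
#'   enhancing lesion).
#' @param k_field_spec list: `mode = "uniform"` with `k`, or
#'   `mode = "quadrants"` with `values` (4 rates, one per quadrant about the
#'   tumor center), 1/day. Negative values indicate net cell death.
#' @param D0 ground-truth diffusion, mm^2/day.
#' @param slice_thickness mm (default 1).
#' @param schedule acquisition days, strictly increasing from 0; default
#'   `c(0, 29, 96, 172)` (the median inter-scan gaps 29/67/76 days).
#' @param initial_fraction peak initial cell fraction at the tumor center
#'   (default 0.75); the profile tapers smoothly to 0 at the tumor rim.
#' @param seed stored for provenance; the construction is deterministic.
#' @return object of class `phantom_truth`.
#' @export
make_phantom <- function(grid_shape = c(64, 64), pixel_spacing = c(1, 1),
                         tumor_spec = list(), k_field_spec = list(mode = "uniform", k = 0),
                         D0 = 1e-2, slice_thickness = 1,
                         schedule = c(0, 29, 96, 172),
                         initial_fraction = 0.75, seed = 0L) {
  stopifnot(all(grid_shape >= 8), all(pixel_spacing > 0),
            schedule[1] == 0, all(diff(schedule) > 0))
  pc <- pixel_coords(grid_shape, pixel_spacing)
  ext <- c(max(pc$x), max(pc$y))
  # breast slice: ellipse filling most of the grid
  bc <- ext / 2
  bax <- 0.48 * ext
  domain <- ((pc$X - bc[1]) / bax[1])^2 + ((pc$Y - bc[2]) / bax[2])^2 <= 1

  center <- if (is.null(tumor_spec$center_mm)) bc else tumor_spec$center_mm
  radius <- if (is.null(tumor_spec$radius_mm)) 10 else tumor_spec$radius_mm
  aspect <- if (is.null(tumor_spec$aspect)) 1 else tumor_spec$aspect
  r2 <- ((pc$X - center[1]) / radius)^2 + ((pc$Y - center[2]) / (radius * aspect))^2
  roi <- r2 <= 1
  if (!any(roi)) stop("tumor specification produced an empty ROI")
  if (any(roi & !domain)) stop("tumor extends outside the breast domain")

  profile <- if (is.null(tumor_spec$profile)) "taper" else tumor_spec$profile
  rr <- sqrt(pmin(r2, 1))
  N0 <- matrix(0, grid_shape[1], grid_shape[2])
  N0[roi] <- switch(profile,
    taper = initial_fraction * cos(pi * rr[roi] / 2)^2,
    plateau = initial_fraction,
    stop("unknown tumor profile: ", profile))

  k_map <- matrix(0, grid_shape[1], grid_shape[2])
  region_id <- matrix(0L, grid_shape[1], grid_shape[2])
  mode <- if (is.null(k_field_spec$mode)) "uniform" else k_field_spec$mode
  if (mode == "uniform") {
    k_map[roi] <- k_field_spec$k
    region_id[roi] <- 1L
  } else if (mode == "quadrants") {
    v <- k_field_spec$values
    stopifnot(length(v) == 4)
    q <- 1L + (pc$X >= center[1]) + 2L * (pc$Y >= center[2])
    k_map[roi] <- v[q[roi]]
    region_id[roi] <- q[roi]
  } else stop("unknown k_field_spec mode: ", mode)

  structure(list(
    domain_mask = domain, roi_mask = roi, N0_frac = N0,
    true_k_map = k_map, region_id_map = region_id, true_D0 = D0,
    pixel_spacing = pixel_spacing, slice_thickness = slice_thickness,
    schedule = schedule, tumor_center = center, tumor_radius = radius,
    grid_shape = grid_shape, seed = seed
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %dx%d grid, ROI %d px (%.1f mm^2), k in [%.3g, %.3g] /day, D0 = %g mm^2/day\n",
              x$grid_shape[1], x$grid_shape[2], sum(x$roi_mask),
              sum(x$roi_mask) * prod(x$pixel_spacing),
              min(x$true_k_map[x$roi_mask]), max(x$true_k_map[x$roi_mask]),
              x$true_D0))
  invisible(x)
}

#' Forward-simulate the phantom cellularity over the acquisition schedule
#'
#' Meshes the tumor plus a 1 cm host-tissue margin, projects the phantom's
#' initial cell field and regional rate map onto the mesh, and runs the
#' coupled growth model with `dt = 1` day, recording the cell field at each
#' scheduled acquisition day.
#'
#' @param phantom a `phantom_truth`.
#' @param params a `model_params`; defaults to the package defaults with the
#'   phantom's `true_D0`.
#' @param schedule acquisition days (default the phantom's schedule).
#' @param target_edge_mm mesh edge target (default 1.5 mm).
#' @param roi_threshold cell fraction above which a pixel counts as tumor at
#'   later time points (default 0.02).
#' @return object of class `cellularity_series`: fraction images and ROI masks
#'   per scheduled day, the mesh, and the nodal trajectory endpoints.
#' @export
simulate_cellularity_series <- function(phantom, params = NULL,
                                        schedule = phantom$schedule,
                                        target_edge_mm = 1.5,
                                        roi_threshold = 0.02) {
  if (is.null(params)) params <- model_params(D0 = phantom$true_D0)
  params$D0 <- if (is.null(params$D0)) phantom$true_D0 else params$D0
  dom <- mesh_domain_mask(phantom$roi_mask, phantom$domain_mask,
                          phantom$pixel_spacing, margin_mm = 10)
  mesh <- build_mesh(dom, phantom$pixel_spacing, target_edge_mm,
                     roi_mask = phantom$roi_mask)
  N0 <- raster_to_nodal(phantom$N0_frac, mesh)
  k_elem <- image_at_elements(phantom$true_k_map, mesh)
  fw <- run_forward(N0, k_elem, mesh, params, max(schedule),
                    record_days = schedule)
  if (fw$max_violation > 1e-6)
    stop(sprintf("unstable step: cell fraction exceeded capacity by %.3g on day %g",
                 fw$max_violation, fw$violation_day))
  imgs <- lapply(seq_along(schedule), function(i) {
    im <- nodal_to_raster(fw$N[, i], mesh, phantom$grid_shape,
                          phantom$pixel_spacing, fill = 0)
    im
  })
  rois <- lapply(imgs, function(im) im > roi_threshold)
  structure(list(times = schedule, frac_images = imgs, roi_per_time = rois,
                 N_nodal = fw$N, mesh = mesh, params = params,
                 phantom = phantom),
            class = "cellularity_series_images")
}

# element-centroid lookup of a pixel image (nearest pixel)
image_at_elements <- function(image, mesh) {
  i <- pmin(pmax(round(mesh$centroids[, 1] / mesh$spacing[1]) + 1L, 1L), nrow(image))
  j <- pmin(pmax(round(mesh$centroids[, 2] / mesh$spacing[2]) + 1L, 1L), ncol(image))
  image[cbind(i, j)]
}

#' Render noisy DW/DCE-MR images from a simulated cellularity series
#'
#' Inverts the cellularity-ADC relation (`ADC = ADC_w - (N/theta) * (ADC_w -
#' adc_min)`), renders the diffusion-weighted signals `S = S0 * exp(-b * ADC)`
#' for each b-value and direction with additive Gaussian noise, and renders
#' pre/post contrast-enhanced images with 100 percent enhancement inside the
#' tumor and 20 percent outside (straddling the 80 percent segmentation
#' threshold).
#'
#' @param series a `cellularity_series_images` from
#'   [simulate_cellularity_series()].
#' @param noise_sigma Gaussian noise standard deviation on the DW signals, in
#'   signal units (S0 = 1000); `S0 / noise_sigma` is the b = 0 SNR.
#' @param adc_min ADC at full cell packing, mm^2/s (default 0.8e-3; must be
#'   below the free-water 3e-3).
#' @param seed RNG seed for the noise.
#' @param b_values acquired b-values, s/mm^2 (default `c(0, 100, 600, 800)`).
#' @param adc_w free-water ADC (default 3e-3 mm^2/s).
#' @param S0 baseline DW signal (default 1000, arbitrary units).
#' @param enhancement in/out contrast enhancement factors (default 2.0 / 1.2).
#' @return object of class `imaging_study`: per time point DW signal arrays
#'   `[nx, ny, n_b, 3]`, DCE pre/post images, b-values, spacing, and the
#'   rendering ground truth.
#' @export
render_images <- function(series, noise_sigma = 0, adc_min = 0.8e-3, seed = 0L,
                          b_values = c(0, 100, 600, 800), adc_w = 3e-3,
                          S0 = 1000, enhancement = c(2.0, 1.2)) {
  stopifnot(inherits(series, "cellularity_series_images"),
            adc_min < adc_w, noise_sigma >= 0)
  phantom <- series$phantom
  gs <- phantom$grid_shape
  dce_base <- 100
  with_preserved_seed(seed, {
    times <- series$times
    dw <- vector("list", length(times))
    dce_pre <- dce_post <- adc_true <- vector("list", length(times))
    for (ti in seq_along(times)) {
      frac <- series$frac_images[[ti]]
      if (max(frac) > 1 + 1e-9)
        stop("cell count exceeds carrying capacity in the series")
      adc <- adc_w - frac * (adc_w - adc_min)
      arr <- array(NA_real_, c(gs[1], gs[2], length(b_values), 3))
      for (bi in seq_along(b_values)) for (d in 1:3) {
        clean <- S0 * exp(-b_values[bi] * adc)
        arr[, , bi, d] <- clean +
          if (noise_sigma > 0) matrix(stats::rnorm(prod(gs), 0, noise_sigma), gs[1], gs[2]) else 0
      }
      roi_t <- series$roi_per_time[[ti]]
      pre <- matrix(dce_base, gs[1], gs[2])
      post <- pre * ifelse(roi_t, enhancement[1], enhancement[2])
      if (noise_sigma > 0) {
        dce_sd <- noise_sigma * dce_base / S0
        pre <- pre + matrix(stats::rnorm(prod(gs), 0, dce_sd), gs[1], gs[2])
        post <- post + matrix(stats::rnorm(prod(gs), 0, dce_sd), gs[1], gs[2])
      }
      dw[[ti]] <- arr
      dce_pre[[ti]] <- pre
      dce_post[[ti]] <- post
      adc_true[[ti]] <- adc
    }
    structure(list(times = times, dw = dw, b_values = b_values,
                   dce_pre = dce_pre, dce_post = dce_post,
                   adc_true = adc_true, roi_per_time = series$roi_per_time,
                   spacing = phantom$pixel_spacing,
                   slice_thickness = phantom$slice_thickness,
                   adc_min = adc_min, adc_w = adc_w, S0 = S0,
                   noise_sigma = noise_sigma, seed = seed),
              class = "imaging_study")
  })
}

#' @export
print.imaging_study <- function(x, ...) {
  cat(sprintf("<imaging_study> %d time points (days %s), b = {%s} s/mm^2, SNR %s\n",
              length(x$times), paste(x$times, collapse = ", "),
              paste(x$b_values, collapse = ", "),
              if (x$noise_sigma > 0) sprintf("%.0f", x$S0 / x$noise_sigma) else "Inf"))
  invisible(x)
}

#' Residual cancer burden outcome record
#'
#' @param rcb_total total RCB index (>= 0; 0 means pathological complete
#'   response).
#' @param rcb_in_breast in-breast RCB (tumor size and cellularity components
#'   only; a separate scale from the total).
#' @return object of class `rcb_outcome` with `is_pcr = (rcb_total == 0)`.
#' @export
rcb_outcome <- function(rcb_total, rcb_in_breast) {
  stopifnot(rcb_total >= 0, rcb_in_breast >= 0)
  structure(list(rcb_total = rcb_total, rcb_in_breast = rcb_in_breast,
                 is_pcr = rcb_total == 0), class = "rcb_outcome")
}

#' Generate a synthetic patient cohort with outcomes
#'
#' Creates `n_patients` phantoms spanning a range of therapy responses (from a
#' complete responder with strongly negative proliferation to a partial
#' responder with residual proliferative regions), simulates their cellularity
#' series, renders imaging, and assigns RCB outcomes as a monotone (linear)
#' noisy function of the final simulated tumor cell burden. The lowest-burden
#' patient is anchored at RCB exactly 0 (pathological complete response);
#' totals span `[0, 3.32]` and in-breast values `[0, 3.0]` by default.
#'
#' @param n_patients at least 3 (default 6).
#' @param response_spec list: `k_range` (base rates for the most/least
#'   responsive patient, default `c(-0.15, 0.03)` 1/day), `heterogeneity`
#'   (quadrant rate spread, default 0.04 1/day), `noise` (outcome noise as a
#'   fraction of the RCB span, default 0), `noise_sigma` (DW image noise,
#'   default 0), `rcb_span` (default 3.32), `in_breast_span` (default 3.0),
#'   `radius_range_mm` (default `c(7, 12)`).
#' @param seed RNG seed; the whole cohort is deterministic given the seed.
#' @param grid_shape,pixel_spacing phantom geometry defaults.
#' @param schedule acquisition days (default `c(0, 29, 96, 172)`).
#' @return object of class `phantom_cohort`: per patient `phantom`, `series`,
#'   `study`, `outcome`, plus an `outcomes` tibble (patient_id, rcb_total,
#'   rcb_in_breast, is_pcr, final_burden).
#' @export
make_cohort <- function(n_patients = 6, response_spec = list(), seed = 0L,
                        grid_shape = c(64, 64), pixel_spacing = c(1, 1),
                        schedule = c(0, 29, 96, 172)) {
  if (n_patients < 3)
    stop("n_patients must be at least 3 (correlation is degenerate below that)")
  rs <- utils::modifyList(list(
    k_range = c(-0.15, 0.03), heterogeneity = 0.04, noise = 0,
    noise_sigma = 0, rcb_span = 3.32, in_breast_span = 3.0,
    radius_range_mm = c(7, 12), outcome_map = "burden",
    profile = "taper", D0 = 1e-2), response_spec)
  with_preserved_seed(seed, {
    base_k <- seq(rs$k_range[1], rs$k_range[2], length.out = n_patients)
    radii <- seq(rs$radius_range_mm[1], rs$radius_range_mm[2],
                 length.out = n_patients)
    spread <- c(-1, -0.3, 0.3, 1) * rs$heterogeneity
    patients <- vector("list", n_patients)
    burden <- numeric(n_patients)
    for (i in seq_len(n_patients)) {
      ph <- make_phantom(grid_shape, pixel_spacing,
                         tumor_spec = list(radius_mm = radii[i],
                                           profile = rs$profile),
                         k_field_spec = list(mode = "quadrants",
                                             values = base_k[i] + spread),
                         D0 = rs$D0,
                         schedule = schedule, seed = seed + i)
      ser <- simulate_cellularity_series(ph)
      study <- render_images(ser, noise_sigma = rs$noise_sigma,
                             seed = seed + 100L + i)
      theta <- carrying_capacity(pixel_spacing, ph$slice_thickness)$theta
      burden[i] <- sum(ser$frac_images[[length(schedule)]]) * theta
      patients[[i]] <- list(phantom = ph, series = ser, study = study)
    }
    u <- switch(rs$outcome_map,
      # RCB linear in the final simulated cell burden (the default):
      # exactly the monotone map the correlation-recovery invariants assume
      burden = (burden - min(burden)) / (max(burden) - min(burden)),
      # RCB linear in the generative response level (base proliferation
      # rate): still monotone in burden, but linear on the scale of the
      # proliferation metrics themselves
      response = (base_k - min(base_k)) / (max(base_k) - min(base_k)),
      stop("unknown outcome_map: ", rs$outcome_map))
    z <- stats::rnorm(n_patients)
    zb <- stats::rnorm(n_patients)
    rcb_tot <- pmax(0, rs$rcb_span * u + rs$noise * rs$rcb_span * z)
    rcb_ib <- pmax(0, rs$in_breast_span * u + rs$noise * rs$in_breast_span * zb)
    rcb_tot[which.min(u)] <- 0
    rcb_ib[which.min(u)] <- 0
    for (i in seq_len(n_patients)) {
      patients[[i]]$outcome <- rcb_outcome(rcb_tot[i], rcb_ib[i])
      patients[[i]]$patient_id <- sprintf("P%02d", i)
    }
    outcomes <- tibble::tibble(
      patient_id = vapply(patients, `[[`, "", "patient_id"),
      rcb_total = rcb_tot, rcb_in_breast = rcb_ib,
      is_pcr = rcb_tot == 0, final_burden = burden)
    structure(list(patients = patients, outcomes = outcomes, seed = seed,
                   response_spec = rs),
              class = "phantom_cohort")
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d patients, RCB total in [%.2f, %.2f], %d pCR\n",
              length(x$patients), min(x$outcomes$rcb_total),
              max(x$outcomes$rcb_total), sum(x$outcomes$is_pcr)))
  invisible(x)
}
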