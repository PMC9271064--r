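#' Write a 2D map as NIfTI with physical spacing in the header
#'
#' @param image numeric matrix.
#' @param path output path (`.nii` / `.nii.gz`).
#' @param spacing mm per pixel (x, y).
#' @param slice_thickness mm (third pixdim), default 1.
#' @return the path, invisibly.
#' @export
write_nifti_map <- function(image, path, spacing, slice_thickness = 1) {
  arr <- array(image, dim = c(dim(image), 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(spacing[1], spacing[2], slice_thickness)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 2D map written by [write_nifti_map()]
#'
#' @param path NIfTI file path.
#' @return list with `values` (matrix) and `spacing` (mm, length 3).
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- if (length(dim(img)) >= 3) img[, , 1] else img[, ]
  pd <- RNifti::pixdim(img)
  list(values = as.matrix(vals), spacing = c(pd, rep(1, max(0, 3 - length(pd)))))
}

#' Write a synthetic imaging study to disk
#'
#' DW signal images per time point, b-value and diffusion direction, and DCE
#' pre/post images, all as NIfTI with spacing in the header.
#'
#' @param study an `imaging_study`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix (e.g. a patient id).
#' @return the directory, invisibly.
#' @export
write_imaging_study <- function(study, dir, prefix = "patient") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ti in seq_along(study$times)) {
    t_lab <- sprintf("T%d", ti - 1)
    for (bi in seq_along(study$b_values)) for (d in 1:3) {
      write_nifti_map(study$dw[[ti]][, , bi, d],
                      file.path(dir, sprintf("%s_%s_dw_b%04d_dir%d.nii.gz",
                                             prefix, t_lab, study$b_values[bi], d)),
                      study$spacing, study$slice_thickness)
    }
    write_nifti_map(study$dce_pre[[ti]],
                    file.path(dir, sprintf("%s_%s_dce_pre.nii.gz", prefix, t_lab)),
                    study$spacing, study$slice_thickness)
    write_nifti_map(study$dce_post[[ti]],
                    file.path(dir, sprintf("%s_%s_dce_post.nii.gz", prefix, t_lab)),
                    study$spacing, study$slice_thickness)
  }
  invisible(dir)
}

#' Write phantom ground truth (JSON scalars + NIfTI fields)
#'
#' @param phantom a `phantom_truth`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return the directory, invisibly.
#' @export
write_phantom_truth <- function(phantom, dir, prefix = "truth") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(true_D0 = phantom$true_D0, schedule = phantom$schedule,
               pixel_spacing = phantom$pixel_spacing,
               slice_thickness = phantom$slice_thickness,
               tumor_center = phantom$tumor_center,
               tumor_radius = phantom$tumor_radius,
               grid_shape = phantom$grid_shape, seed = phantom$seed)
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  sp <- phantom$pixel_spacing; st <- phantom$slice_thickness
  write_nifti_map(phantom$true_k_map, file.path(dir, paste0(prefix, "_k.nii.gz")), sp, st)
  write_nifti_map(phantom$N0_frac, file.path(dir, paste0(prefix, "_N0.nii.gz")), sp, st)
  write_nifti_map(phantom$roi_mask * 1, file.path(dir, paste0(prefix, "_roi.nii.gz")), sp, st)
  write_nifti_map(phantom$domain_mask * 1, file.path(dir, paste0(prefix, "_domain.nii.gz")), sp, st)
  invisible(dir)
}

#' Write a synthetic cohort (images, truth, outcome table)
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients) {
    write_imaging_study(p$study, file.path(dir, p$patient_id), p$patient_id)
    write_phantom_truth(p$phantom, file.path(dir, p$patient_id),
                        paste0(p$patient_id, "_truth"))
  }
  readr::write_csv(
    dplyr::select(cohort$outcomes, "patient_id", "rcb_total",
                  "rcb_in_breast", "is_pcr"),
    file.path(dir, "outcomes.csv"))
  invisible(dir)
}

# CSVs, fit diagnostics JSON, NIfTI parameter maps and (where a png device is
# available) figures for a finished pipeline run.
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$metrics_table, file.path(outdir, "metrics.csv"))
  readr::write_csv(result$cohort_table, file.path(outdir, "cohort_table.csv"))
  readr::write_csv(result$report$r_table, file.path(outdir, "correlation_r.csv"))
  readr::write_csv(result$report$p_table, file.path(outdir, "correlation_p.csv"))
  readr::write_csv(result$report$p_flagged, file.path(outdir, "correlation_p_flagged.csv"))
  diagnostics <- lapply(result$per_patient, function(pp) {
    lapply(pp$fits, function(f)
      list(pair = f$pair_label, D0_hat = f$D0_hat, objective = f$objective,
           converged = f$converged, n_iterations = f$n_iterations,
           k_range = range(f$k_regions)))
  })
  jsonlite::write_json(diagnostics, file.path(outdir, "fit_diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  sp <- result$config$cohort$pixel_spacing
  for (pid in names(result$per_patient)) {
    pp <- result$per_patient[[pid]]
    pdir <- file.path(outdir, pid)
    dir.create(pdir, showWarnings = FALSE)
    gs <- dim(pp$roi[[which(!vapply(pp$roi, is.null, TRUE))[1]]])
    for (ti in which(!vapply(pp$adc, is.null, TRUE))) {
      adc_img <- pp$adc[[ti]]$values
      adc_img[!is.finite(adc_img)] <- 0
      write_nifti_map(adc_img, file.path(pdir, sprintf("adc_T%d.nii.gz", ti - 1)), sp)
      cell_img <- pp$cell[[ti]]$values
      cell_img[is.na(cell_img)] <- 0
      write_nifti_map(cell_img, file.path(pdir, sprintf("cellularity_T%d.nii.gz", ti - 1)), sp)
    }
    for (pl in names(pp$fits)) {
      k_elem <- k_regions_to_elements(pp$fits[[pl]]$k_regions, pp$partition,
                                      nrow(pp$mesh$triangles))
      k_node <- as.vector(node_element_weights(pp$mesh) %*% k_elem)
      k_img <- nodal_to_raster(k_node, pp$mesh, gs, sp, fill = 0)
      write_nifti_map(k_img, file.path(pdir, sprintf("k_map_%s.nii.gz", pl)), sp)
    }
  }
  if (isTRUE(capabilities("png")[[1]])) {
    for (pid in names(result$per_patient)) {
      pp <- result$per_patient[[pid]]
      for (pl in names(pp$fits)) {
        try({
          g1 <- plot_proliferation_map(pp$fits[[pl]], pp$mesh)
          ggplot2::ggsave(file.path(outdir, pid,
                                    sprintf("k_map_%s.png", pl)),
                          g1, width = 5, height = 4, dpi = 120)
          g2 <- ggplot2::autoplot(pp$hists[[pl]])
          ggplot2::ggsave(file.path(outdir, pid,
                                    sprintf("k_hist_%s.png", pl)),
                          g2, width = 5, height = 4, dpi = 120)
        }, silent = TRUE)
      }
    }
  }
  invisible(outdir)
}
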