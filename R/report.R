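#' Pearson correlation with two-sided t-test p-value
#'
#' `r` is the sample Pearson coefficient; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` against the t distribution with
#' `n - 2` degrees of freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length (n >= 3, non-zero variance).
#' @param metric,pair_label,outcome_kind optional labels carried into the
#'   result row.
#' @return one-row tibble of class `correlation_result`: `metric`,
#'   `pair_label`, `outcome_kind`, `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y, metric = NA_character_,
                                pair_label = NA_character_,
                                outcome_kind = NA_character_) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("Pearson correlation needs at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- .Machine$double.xmin  # numerical floor for exact linearity
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  out <- tibble::tibble(metric = metric, pair_label = pair_label,
                        outcome_kind = outcome_kind,
                        r = r, p = p, n = n)
  class(out) <- c("correlation_result", class(out))
  out
}

significance_flag <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' Correlation report over a cohort metric table
#'
#' For every metric x time-point-pair x outcome cell, computes the Pearson
#' correlation between the per-patient metric values and the RCB outcome, and
#' lays the results out as one `r` table and one `p` table (rows = metrics,
#' columns = pair x outcome) with significance flags (`*` p < 0.05, `**`
#' p < 0.01).
#'
#' @param cohort_table tibble with columns `patient_id`, `pair_label`,
#'   `metric`, `value`, `rcb_total`, `rcb_in_breast`.
#' @param metrics metrics (rows) to report, in order; defaults to all present.
#' @return object of class `cohort_report`: `correlations` (long tibble with
#'   `r`, `p`, `n`, `flag`), `r_table`, `p_table` (wide tibbles), and
#'   `p_flagged` (p values formatted with stars).
#' @export
build_report <- function(cohort_table, metrics = NULL) {
  req <- c("patient_id", "pair_label", "metric", "value",
           "rcb_total", "rcb_in_breast")
  stopifnot(all(req %in% names(cohort_table)))
  if (any(duplicated(cohort_table[, c("patient_id", "pair_label", "metric")])))
    stop("duplicate (patient, pair, metric) keys in cohort table")
  if (is.null(metrics)) metrics <- unique(cohort_table$metric)
  pairs <- unique(cohort_table$pair_label)

  cells <- tidyr::expand_grid(metric = metrics, pair_label = pairs,
                              outcome_kind = c("total", "in_breast"))
  correlations <- purrr::pmap_dfr(cells, function(metric, pair_label, outcome_kind) {
    sub <- dplyr::filter(cohort_table, .data$metric == !!metric,
                         .data$pair_label == !!pair_label)
    y <- if (outcome_kind == "total") sub$rcb_total else sub$rcb_in_breast
    ok <- is.finite(sub$value) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(sub$value[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning(sprintf("correlation cell %s/%s/%s is degenerate; reported as NA",
                      metric, pair_label, outcome_kind))
      return(tibble::tibble(metric = metric, pair_label = pair_label,
                            outcome_kind = outcome_kind,
                            r = NA_real_, p = NA_real_, n = sum(ok)))
    }
    pearson_correlation(sub$value[ok], y[ok], metric, pair_label, outcome_kind)
  })
  correlations$flag <- significance_flag(correlations$p)

  wide <- function(col) {
    correlations |>
      dplyr::mutate(column = paste(.data$pair_label, .data$outcome_kind, sep = "_")) |>
      dplyr::select("metric", "column", dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "column", values_from = dplyr::all_of(col)) |>
      dplyr::arrange(match(.data$metric, metrics))
  }
  p_flagged <- correlations |>
    dplyr::mutate(cell = ifelse(is.na(.data$p), "NA",
                                sprintf("%.4f%s", .data$p, .data$flag)),
                  column = paste(.data$pair_label, .data$outcome_kind, sep = "_")) |>
    dplyr::select("metric", "column", "cell") |>
    tidyr::pivot_wider(names_from = "column", values_from = "cell") |>
    dplyr::arrange(match(.data$metric, metrics))

  structure(list(correlations = correlations, r_table = wide("r"),
                 p_table = wide("p"), p_flagged = p_flagged),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Pearson correlation coefficients (metric vs RCB):\n")
  print(as.data.frame(x$r_table), digits = 4, row.names = FALSE)
  cat("\np-values (* p < 0.05, ** p < 0.01):\n")
  print(as.data.frame(x$p_flagged), row.names = FALSE)
  invisible(x)
}

#' Default pipeline configuration
#'
#' Returns the nested configuration list consumed by [run_pipeline()], with
#' the acquisition and model settings used throughout the package: b-values
#' {0, 100, 600, 800} s/mm^2 with ADC fit at b = 800, 80 percent enhancement
#' segmentation, 1.5 mm mesh edges, 5 elements per region, dt = 1 day, and
#' the T01/T12/T02 time-point pairs over the schedule {0, 29, 96, 172} days.
#'
#' @param ... named overrides merged (recursively) into the defaults.
#' @return nested list.
#' @export
default_config <- function(...) {
  cfg <- list(
    cohort = list(n_patients = 6, response_spec = list(), seed = 1L,
                  grid_shape = c(48, 48), pixel_spacing = c(1, 1),
                  schedule = c(0, 29, 96, 172)),
    imaging = list(b_select = 800, adc_w = 3e-3, seed_margin_mm = 5),
    mesh = list(target_edge_mm = 1.5, elements_per_region = 5,
                margin_mm = 10, kmeans_seed = 0L),
    model = list(gamma = 1.0, lam = 1e-3, E = 2.0, nu = 0.45, dt = 1),
    inverse = list(init = list(), bounds = list(),
                   control = list(maxit = 200L)),
    metrics = list(bin_width = 0.1, delta_mode = "percent",
                   table_metrics = c("mean", "median", "p75",
                                     "delta_longest_dimension",
                                     "delta_mean_adc", "delta_ftv")),
    pairs = c("T01", "T12", "T02"),
    outdir = NULL)
  utils::modifyList(cfg, list(...))
}

pair_time_indices <- function(pair_label) {
  switch(pair_label,
         T01 = c(1L, 2L), T12 = c(2L, 3L), T02 = c(1L, 3L),
         T23 = c(3L, 4L), T03 = c(1L, 4L), T13 = c(2L, 4L),
         stop("unknown pair label: ", pair_label))
}

# Full per-patient analysis: ADC maps, ROIs, cellularity, per-pair fits and
# metrics. Returns a list with the intermediate objects and a metrics tibble.
analyze_patient <- function(patient, cfg) {
  phantom <- patient$phantom
  study <- patient$study
  spacing <- study$spacing
  theta <- carrying_capacity(spacing, study$slice_thickness)$theta
  needed <- sort(unique(unlist(lapply(cfg$pairs, pair_time_indices))))
  seed_mask <- dilate_mask(phantom$roi_mask, spacing,
                           cfg$imaging$seed_margin_mm) & phantom$domain_mask

  # A fully responding tumor stops enhancing: an empty segmentation at a
  # later time point means zero residual cellularity there, not a failure.
  adc <- roi <- vector("list", max(needed))
  for (ti in needed) {
    adc[[ti]] <- compute_adc(study$dw[[ti]], study$b_values,
                             b_select = cfg$imaging$b_select)
    roi[[ti]] <- tryCatch(
      segment_tumor(study$dce_pre[[ti]], study$dce_post[[ti]], seed_mask),
      prolifmap_empty_roi = function(e) {
        matrix(FALSE, nrow(seed_mask), ncol(seed_mask))
      })
  }
  if (!any(roi[[needed[1]]]))
    stop("no enhancing tumor at the baseline time point")
  adc_min_pat <- min(vapply(needed[vapply(needed, function(ti) any(roi[[ti]]), TRUE)],
                            function(ti) {
    inside <- roi[[ti]] & adc[[ti]]$valid_mask
    min(adc[[ti]]$values[inside])
  }, 0))
  cell <- vector("list", max(needed))
  for (ti in needed) {
    cell[ti] <- list(if (any(roi[[ti]])) {
      cellularity_from_adc(adc[[ti]], roi[[ti]], theta,
                           adc_w = cfg$imaging$adc_w, adc_min = adc_min_pat)
    } else NULL)
  }

  roi_union <- Reduce(`|`, roi[needed])
  dom <- mesh_domain_mask(roi_union, phantom$domain_mask, spacing,
                          margin_mm = cfg$mesh$margin_mm)
  mesh <- build_mesh(dom, spacing, cfg$mesh$target_edge_mm,
                     roi_mask = roi_union)
  partition <- partition_regions(mesh,
                                 elements_per_region = cfg$mesh$elements_per_region,
                                 seed = cfg$mesh$kmeans_seed)
  params <- model_params(gamma = cfg$model$gamma, lam = cfg$model$lam,
                         E = cfg$model$E, nu = cfg$model$nu,
                         theta = theta, dt = cfg$model$dt)

  frac_of <- function(ti) {
    if (ti > length(cell) || is.null(cell[[ti]]))
      return(matrix(0, nrow(seed_mask), ncol(seed_mask)))
    f <- cell[[ti]]$values / theta
    f[is.na(f)] <- 0
    f
  }
  # conventional metrics with tumor-bed fallbacks for a vanished tumor:
  # size metrics go to 0; mean ADC is read over the baseline tumor bed
  ld_of <- function(ti) if (any(roi[[ti]])) longest_dimension(roi[[ti]], spacing) else 0
  adc_of <- function(ti) {
    bed <- if (any(roi[[ti]])) roi[[ti]] else roi[[needed[1]]]
    mean_tumor_adc(adc[[ti]], bed)
  }
  fits <- list(); hists <- list(); rows <- list()
  for (pl in cfg$pairs) {
    id <- pair_time_indices(pl)
    interval <- study$times[id[2]] - study$times[id[1]]
    Ns <- pmin(pmax(raster_to_nodal(frac_of(id[1]), mesh), 0), 1)
    Ne <- pmin(pmax(raster_to_nodal(frac_of(id[2]), mesh), 0), 1)
    pair_roi <- roi[[id[1]]] | roi[[id[2]]]
    roi_nodes <- which(mask_at_points(pair_roi, spacing, mesh$nodes))
    pair <- observation_pair(Ns, Ne, interval, pl, roi_nodes = roi_nodes)
    fit <- estimate_proliferation(pair, mesh, partition, params,
                                  init = cfg$inverse$init,
                                  bounds = cfg$inverse$bounds,
                                  control = cfg$inverse$control)
    hs <- proliferation_histogram(fit, partition, mesh,
                                  bin_width = cfg$metrics$bin_width)
    dm <- cfg$metrics$delta_mode
    conv <- c(
      delta_longest_dimension = delta_metric(ld_of(id[1]), ld_of(id[2]), dm),
      delta_mean_adc = delta_metric(adc_of(id[1]), adc_of(id[2]), dm),
      delta_ftv = delta_metric(
        functional_tumor_volume(roi[[id[1]]], spacing, study$slice_thickness),
        functional_tumor_volume(roi[[id[2]]], spacing, study$slice_thickness), dm))
    fits[[pl]] <- fit
    hists[[pl]] <- hs
    rows[[pl]] <- tibble::tibble(
      patient_id = patient$patient_id, pair_label = pl,
      metric = c("mean", "median", "iqr", "std", "p25", "p75", names(conv)),
      value = c(hs$mean, hs$median, hs$iqr, hs$std, hs$p25, hs$p75,
                unname(conv)))
  }
  list(patient_id = patient$patient_id, adc = adc, roi = roi, cell = cell,
       mesh = mesh, partition = partition, fits = fits, hists = hists,
       theta = theta, adc_min = adc_min_pat,
       metrics = dplyr::bind_rows(rows))
}

#' Run the full analysis pipeline on a cohort
#'
#' For each patient: ADC maps, enhancement-based tumor ROIs, cellularity maps,
#' regional proliferation fits for every requested time-point pair, histogram
#' and conventional metrics; then cohort-level Pearson correlation of every
#' metric with total and in-breast RCB. A per-patient failure is isolated,
#' reported as a warning, and that patient is excluded from the correlation
#' stage.
#'
#' @param config nested configuration list from [default_config()].
#' @param cohort optional precomputed `phantom_cohort`; generated from
#'   `config$cohort` when missing.
#' @return object of class `pipeline_result`: `per_patient` analyses,
#'   `metrics_table`, `cohort_table`, `report` (a `cohort_report`),
#'   `excluded`, `config`, and the cohort `outcomes`.
#' @export
run_pipeline <- function(config = default_config(), cohort = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cohort))
    cohort <- make_cohort(n_patients = cfg$cohort$n_patients,
                          response_spec = cfg$cohort$response_spec,
                          seed = cfg$cohort$seed,
                          grid_shape = cfg$cohort$grid_shape,
                          pixel_spacing = cfg$cohort$pixel_spacing,
                          schedule = cfg$cohort$schedule)
  per_patient <- list(); excluded <- character(0)
  for (p in cohort$patients) {
    res <- tryCatch(analyze_patient(p, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("patient %s excluded: %s", p$patient_id,
                      conditionMessage(res)))
      excluded <- c(excluded, p$patient_id)
    } else per_patient[[p$patient_id]] <- res
  }
  if (!length(per_patient)) stop("no patient could be analyzed")
  metrics_table <- dplyr::bind_rows(lapply(per_patient, `[[`, "metrics"))
  cohort_table <- dplyr::inner_join(metrics_table, cohort$outcomes,
                                    by = "patient_id")
  report <- build_report(cohort_table, metrics = cfg$metrics$table_metrics)
  out <- structure(list(per_patient = per_patient,
                        metrics_table = metrics_table,
                        cohort_table = cohort_table, report = report,
                        excluded = excluded, outcomes = cohort$outcomes,
                        config = cfg),
                   class = "pipeline_result")
  if (!is.null(cfg$outdir)) write_pipeline_outputs(out, cfg$outdir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d patients analyzed (%d excluded), pairs: %s\n\n",
              length(x$per_patient), length(x$excluded),
              paste(x$config$pairs, collapse = ", ")))
  print(x$report)
  invisible(x)
}
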