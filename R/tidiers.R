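#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a proliferation fit into one row per region
#'
#' @param x a `prolif_fit`.
#' @param ... unused.
#' @return tibble with `region`, `k` (1/day), `area_mm2`, `n_elements`.
#' @method tidy prolif_fit
#' @export
tidy.prolif_fit <- function(x, ...) {
  part <- x$partition
  tibble::tibble(
    region = seq_along(x$k_regions),
    k = x$k_regions,
    area_mm2 = part$region_areas[seq_along(x$k_regions)],
    n_elements = as.integer(table(factor(part$region_of_element,
                                         levels = seq_along(x$k_regions)))))
}

#' One-row summary of a proliferation fit
#'
#' @param x a `prolif_fit`.
#' @param ... unused.
#' @return tibble with `pair_label`, `D0_hat`, `objective`, `converged`,
#'   `n_iterations`, `n_regions`.
#' @method glance prolif_fit
#' @export
glance.prolif_fit <- function(x, ...) {
  tibble::tibble(pair_label = x$pair_label, D0_hat = x$D0_hat,
                 objective = x$objective, converged = x$converged,
                 n_iterations = x$n_iterations,
                 n_regions = length(x$k_regions))
}

#' Tidy a proliferation histogram into one row per bin
#'
#' @param x a `hist_summary`.
#' @param ... unused.
#' @return tibble with `bin_left`, `bin_right`, `bin_mid` (1/day) and
#'   `weight` (mm^2 of tumor at that rate).
#' @method tidy hist_summary
#' @export
tidy.hist_summary <- function(x, ...) {
  ne <- length(x$bin_edges)
  tibble::tibble(bin_left = x$bin_edges[-ne], bin_right = x$bin_edges[-1],
                 bin_mid = (x$bin_edges[-ne] + x$bin_edges[-1]) / 2,
                 weight = x$bin_counts)
}

#' One-row summary metrics of a proliferation histogram
#'
#' @param x a `hist_summary`.
#' @param ... unused.
#' @return tibble with `mean`, `median`, `iqr`, `std`, `p25`, `p75` (1/day).
#' @method glance hist_summary
#' @export
glance.hist_summary <- function(x, ...) {
  tibble::tibble(mean = x$mean, median = x$median, iqr = x$iqr,
                 std = x$std, p25 = x$p25, p75 = x$p75)
}

#' Tidy the correlation cells of a cohort report
#'
#' @param x a `cohort_report`.
#' @param ... unused.
#' @return the long correlations tibble (`metric`, `pair_label`,
#'   `outcome_kind`, `r`, `p`, `n`, `flag`).
#' @method tidy cohort_report
#' @export
tidy.cohort_report <- function(x, ...) x$correlations

#' Per-patient metric table of a pipeline run
#'
#' @param x a `pipeline_result`.
#' @param ... unused.
#' @return the cohort table joining metrics with outcomes.
#' @method tidy pipeline_result
#' @export
tidy.pipeline_result <- function(x, ...) x$cohort_table

#' One-row summary of a pipeline run
#'
#' @param x a `pipeline_result`.
#' @param ... unused.
#' @return tibble with patient counts and the strongest correlation found.
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  co <- x$report$correlations
  best <- co[which.max(abs(co$r)), ]
  tibble::tibble(n_patients = length(x$per_patient),
                 n_excluded = length(x$excluded),
                 n_pairs = length(x$config$pairs),
                 best_metric = best$metric, best_pair = best$pair_label,
                 best_outcome = best$outcome_kind, best_r = best$r,
                 best_p = best$p)
}
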