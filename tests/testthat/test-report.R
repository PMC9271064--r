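test_that("pearson correlation handles exact linearity and rejects degenerate input", {
  x <- c(1, 2, 3, 4, 5, 6)
  r1 <- pearson_correlation(x, 2 * x + 1)
  expect_equal(r1$r, 1)
  expect_lt(r1$p, 1e-12)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x[1:2], x[1:2]), "at least 3")
  expect_error(pearson_correlation(x, rep(1, 6)), "variance")
})

test_that("pearson agrees with brute-force covariance computation", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- pearson_correlation(x, y)
    r_brute <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(r$r, r_brute, tolerance = 1e-12)
    expect_equal(r$p, stats::cor.test(x, y)$p.value, tolerance = 1e-9)
  }
})

test_that("an observed r on correlated draws sits inside its sampling distribution", {
  # generative correlation rho = 0.6, n = 6: compare one draw against the
  # Monte-Carlo central 99 percent interval of the sampling distribution
  rho <- 0.6; n <- 6
  set.seed(123)
  draw_r <- function() {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    pearson_correlation(x, y)$r
  }
  r_obs <- draw_r()
  rs <- replicate(4000, draw_r())
  ci <- stats::quantile(rs, c(0.005, 0.995))
  expect_gte(r_obs, ci[[1]])
  expect_lte(r_obs, ci[[2]])
})

fake_cohort_table <- function() {
  # 6 patients, 2 pairs, 2 metrics; outcome exactly linear in metric "mean"
  patients <- sprintf("P%02d", 1:6)
  base <- tidyr::expand_grid(patient_id = patients,
                             pair_label = c("T01", "T02"),
                             metric = c("mean", "median"))
  val <- seq(-0.1, 0.05, length.out = 6)
  base$value <- val[match(base$patient_id, patients)] +
    ifelse(base$metric == "median", 0.01, 0) +
    ifelse(base$pair_label == "T02", 0.002, 0)
  out <- tibble::tibble(patient_id = patients,
                        rcb_total = 3.32 * (val - min(val)) / diff(range(val)),
                        rcb_in_breast = 3 * (val - min(val)) / diff(range(val)))
  dplyr::inner_join(base, out, by = "patient_id")
}

test_that("report tables carry r, p and significance stars per cell", {
  tab <- fake_cohort_table()
  rep <- build_report(tab)
  expect_equal(nrow(rep$correlations), 2 * 2 * 2)
  expect_true(all(abs(rep$correlations$r - 1) < 1e-12))
  expect_true(all(rep$correlations$flag == "**"))
  expect_named(rep$r_table,
               c("metric", "T01_total", "T01_in_breast", "T02_total",
                 "T02_in_breast"))
  expect_equal(significance_flag <- prolifmap:::significance_flag(c(0.049, 0.009, 0.2)),
               c("*", "**", ""))
  # shuffling patients leaves the tables unchanged
  rep2 <- build_report(tab[sample(nrow(tab)), ])
  expect_equal(rep$r_table, rep2$r_table)
  expect_equal(rep$p_table, rep2$p_table)
  # a degenerate cell is reported as NA with a warning
  tab2 <- tab
  tab2$value[tab2$metric == "median"] <- 1
  w <- capture_warnings(rep3 <- build_report(tab2))
  expect_true(length(w) > 0 && all(grepl("degenerate", w)))
  expect_true(all(is.na(dplyr::filter(rep3$correlations,
                                      .data$metric == "median")$r)))
  # duplicate keys are rejected
  expect_error(build_report(rbind(tab, tab[1, ])), "duplicate")
})

small_cfg <- function(pairs = "T01") {
  default_config(
    cohort = list(n_patients = 3, seed = 9, grid_shape = c(36, 36),
                  response_spec = list(radius_range_mm = c(5.5, 7),
                                       profile = "plateau",
                                       k_range = c(-0.08, 0.02), D0 = 1e-3)),
    inverse = list(control = list(maxit = 60L)),
    pairs = pairs)
}

test_that("the pipeline emits complete, pair-restricted, deterministic outputs", {
  d1 <- withr::local_tempdir()
  cfg <- small_cfg()
  cfg$outdir <- d1
  res <- run_pipeline(cfg)
  expect_length(res$per_patient, 3)
  # only T01 columns appear when only T01 is requested
  expect_named(res$report$r_table, c("metric", "T01_total", "T01_in_breast"))
  # 6 table metrics x 1 pair x 2 outcomes correlation cells
  expect_equal(nrow(res$report$correlations), 6 * 1 * 2)
  expect_true(all(c("metrics.csv", "correlation_r.csv", "fit_diagnostics.json")
                  %in% list.files(d1)))
  # per-patient parameter maps are written as NIfTI
  expect_true(file.exists(file.path(d1, "P01", "k_map_T01.nii.gz")))
  # rerun with the same seeds: byte-identical CSV outputs
  d2 <- withr::local_tempdir()
  cfg2 <- small_cfg()
  cfg2$outdir <- d2
  run_pipeline(cfg2)
  for (f in c("metrics.csv", "correlation_r.csv", "correlation_p.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
})

test_that("a failing patient is excluded with a warning, not fatal", {
  cfg <- small_cfg()
  cfg$cohort$n_patients <- 4
  co <- make_cohort(n_patients = 4, response_spec = cfg$cohort$response_spec,
                    seed = cfg$cohort$seed, grid_shape = cfg$cohort$grid_shape)
  # destroy one patient's baseline enhancement: segmentation must fail there
  for (ti in seq_along(co$patients[[2]]$study$times))
    co$patients[[2]]$study$dce_post[[ti]] <- co$patients[[2]]$study$dce_pre[[ti]]
  w <- capture_warnings(res <- run_pipeline(cfg, cohort = co))
  expect_true(any(grepl("P02 excluded", w)))
  expect_length(res$per_patient, 3)
  expect_identical(res$excluded, "P02")
  expect_false("P02" %in% res$cohort_table$patient_id)
  expect_s3_class(res$report, "cohort_report")
})

test_that("a cohort exports images, truth and the outcome table", {
  co <- make_cohort(n_patients = 3, seed = 2, grid_shape = c(36, 36),
                    response_spec = list(radius_range_mm = c(6, 7)))
  co$patients <- co$patients[1]  # keep the export small
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  out <- readr::read_csv(file.path(dir, "outcomes.csv"), show_col_types = FALSE)
  expect_named(out, c("patient_id", "rcb_total", "rcb_in_breast", "is_pcr"))
  expect_equal(nrow(out), 3)
  files <- list.files(file.path(dir, "P01"))
  expect_true(any(grepl("dw_b0800_dir3", files)))
  expect_true(any(grepl("dce_post", files)))
  expect_true(any(grepl("truth_meta.json", files)))
})

test_that("the pipeline computes every requested pair and tidies into tibbles", {
  res <- run_pipeline(small_cfg(pairs = c("T01", "T12")))
  expect_setequal(unique(res$metrics_table$pair_label), c("T01", "T12"))
  expect_equal(nrow(res$report$correlations), 6 * 2 * 2)
  expect_s3_class(tidy(res), "tbl_df")
  expect_s3_class(glance(res), "tbl_df")
  ft <- res$per_patient[[1]]$fits[["T01"]]
  expect_s3_class(tidy(ft), "tbl_df")
  expect_equal(nrow(tidy(ft)), length(ft$k_regions))
  expect_s3_class(autoplot(res$per_patient[[1]]$hists[["T01"]]), "ggplot")
  expect_s3_class(plot_proliferation_map(ft, res$per_patient[[1]]$mesh), "ggplot")
  expect_s3_class(plot_cohort_correlations(res), "ggplot")
})
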