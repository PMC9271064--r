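test_that("phantom construction honors geometry, heterogeneity and determinism", {
  ph <- make_phantom(c(64, 64), c(1, 1), tumor_spec = list(radius_mm = 5),
                     k_field_spec = list(mode = "uniform", k = 0))
  # rasterized disc area close to pi r^2
  expect_lt(abs(sum(ph$roi_mask) - pi * 25) / (pi * 25), 0.06)
  expect_true(all(ph$domain_mask[ph$roi_mask]))
  expect_true(all(diff(ph$schedule) > 0) && ph$schedule[1] == 0)
  ph2 <- make_phantom(c(64, 64), c(1, 1), tumor_spec = list(radius_mm = 5),
                      k_field_spec = list(mode = "uniform", k = 0))
  expect_identical(ph, ph2)
  phq <- make_phantom(c(64, 64), c(1, 1), tumor_spec = list(radius_mm = 8),
                      k_field_spec = list(mode = "quadrants",
                                          values = c(-0.1, -0.02, 0.05, 0.2)))
  expect_setequal(unique(phq$true_k_map[phq$roi_mask]),
                  c(-0.1, -0.02, 0.05, 0.2))
  expect_true(any(phq$true_k_map[phq$roi_mask] < 0) &&
              any(phq$true_k_map[phq$roi_mask] > 0))
  # tumor must fit inside the breast, and must not be empty
  expect_error(make_phantom(c(64, 64), c(1, 1),
                            tumor_spec = list(center_mm = c(2, 2), radius_mm = 8)),
               "outside")
  expect_error(make_phantom(c(64, 64), c(1, 1),
                            tumor_spec = list(center_mm = c(-30, -30), radius_mm = 0.01)),
               "empty|outside")
})

test_that("simulated series is constant without dynamics and bounded with them", {
  ph <- make_phantom(c(40, 40), c(1, 1), tumor_spec = list(radius_mm = 7),
                     k_field_spec = list(mode = "uniform", k = 0), D0 = 0)
  ser <- simulate_cellularity_series(ph, params = model_params(D0 = 0, gamma = 0),
                                     schedule = c(0, 29, 60))
  for (i in 2:3)
    expect_equal(ser$frac_images[[i]], ser$frac_images[[1]], tolerance = 1e-10)
  fx <- fx_study()
  for (im in fx$series$frac_images)
    expect_true(all(im >= 0 & im <= 1 + 1e-9))
})

test_that("a positive-rate region gains cells over the interval", {
  # slow motility phantom (D0 = 1e-3): the +0.02/day quadrant outgrows its
  # small diffusive exchange with the decaying neighbors
  fx <- fx_recovery()
  pos <- fx$phantom$true_k_map > 0 & fx$phantom$roi_mask
  n0 <- sum(fx$series$frac_images[[1]][pos])
  n1 <- sum(fx$series$frac_images[[2]][pos])
  expect_gt(n1, n0)
  # against a fine-step forward oracle of the same run
  pf <- model_params(D0 = 1e-3, gamma = 1, lam = 1e-3, dt = 0.1, theta = 1)
  ke <- prolifmap:::image_at_elements(fx$phantom$true_k_map, fx$mesh)
  fwf <- run_forward(fx$series$N_nodal[, 1], ke, fx$mesh, pf, 29)
  coarse <- run_forward(fx$series$N_nodal[, 1], ke, fx$mesh,
                        model_params(D0 = 1e-3, gamma = 1, lam = 1e-3, theta = 1),
                        29)
  expect_lt(max(abs(coarse$N[, 2] - fwf$N[, 2])) / max(fwf$N[, 2]), 0.01)
})

test_that("rendered images invert exactly at zero noise", {
  fx <- fx_study()
  st <- fx$study
  # implied ADC endpoints
  ti <- 1
  frac <- fx$series$frac_images[[ti]]
  expect_equal(st$adc_true[[ti]][frac == 0][1], 3e-3)
  adc <- compute_adc(st$dw[[ti]], st$b_values, 800)
  expect_lt(max(abs(adc$values - st$adc_true[[ti]]) / st$adc_true[[ti]]), 1e-10)
  # DW signal strictly decreases with b (noise-free), all directions
  for (d in 1:3) {
    s <- st$dw[[ti]][20, 20, , d]
    expect_true(all(diff(s) < 0))
  }
  # cellularity round trip through the ADC map is the identity on the ROI
  th <- carrying_capacity(c(1, 1), 1)$theta
  roi <- fx$series$roi_per_time[[ti]]
  cm <- cellularity_from_adc(adc, roi, th, adc_min = st$adc_min)
  expect_lt(max(abs(cm$values[roi] / th - frac[roi])), 1e-10)
  # renderer rejects super-capacity fields
  bad <- fx$series
  bad$frac_images[[1]][20, 20] <- 1.5
  expect_error(render_images(bad, noise_sigma = 0), "capacity")
  # determinism under a fixed seed
  s1 <- render_images(fx$series, noise_sigma = 30, seed = 11)
  s2 <- render_images(fx$series, noise_sigma = 30, seed = 11)
  expect_identical(s1$dw, s2$dw)
})

test_that("contrast enhancement straddles the segmentation threshold", {
  fx <- fx_study()
  st <- fx$study
  roi <- fx$series$roi_per_time[[1]]
  ratio <- st$dce_post[[1]] / st$dce_pre[[1]]
  expect_true(all(ratio[roi] >= 1.8))
  expect_true(all(ratio[!roi] < 1.8))
})

test_that("cohort generation produces the documented outcome structure", {
  co <- make_cohort(n_patients = 3, seed = 5, grid_shape = c(36, 36),
                    response_spec = list(radius_range_mm = c(6, 8)))
  expect_length(co$patients, 3)
  expect_true(any(co$outcomes$is_pcr))
  expect_true(all(co$outcomes$is_pcr == (co$outcomes$rcb_total == 0)))
  expect_true(all(co$outcomes$rcb_total >= 0 & co$outcomes$rcb_in_breast >= 0))
  expect_equal(max(co$outcomes$rcb_total), 3.32, tolerance = 1e-9)
  # with zero outcome noise the map is exactly linear in final burden
  r <- cor(co$outcomes$final_burden, co$outcomes$rcb_total)
  expect_equal(r, 1, tolerance = 1e-12)
  expect_equal(order(co$outcomes$rcb_total), order(co$outcomes$final_burden))
  # determinism
  co2 <- make_cohort(n_patients = 3, seed = 5, grid_shape = c(36, 36),
                     response_spec = list(radius_range_mm = c(6, 8)))
  expect_identical(co$outcomes, co2$outcomes)
  expect_identical(co$patients[[2]]$study$dw, co2$patients[[2]]$study$dw)
  expect_error(make_cohort(n_patients = 2), "at least 3")
})

test_that("study and truth round-trip through NIfTI with spacing preserved", {
  fx <- fx_study()
  dir <- withr::local_tempdir()
  write_nifti_map(fx$series$frac_images[[1]], file.path(dir, "frac.nii.gz"),
                  c(1, 1), 1)
  back <- read_nifti_map(file.path(dir, "frac.nii.gz"))
  expect_equal(back$values, fx$series$frac_images[[1]], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$spacing[1:2], c(1, 1))
  write_phantom_truth(fx$phantom, dir)
  meta <- jsonlite::read_json(file.path(dir, "truth_meta.json"))
  expect_equal(meta$true_D0, fx$phantom$true_D0)
})
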