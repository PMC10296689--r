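test_that("cohort generation is deterministic and internally consistent", {
  cfg <- simulation_config(n_patients = 3)
  a <- simulate_cohort(cfg, seed = 7)
  b <- simulate_cohort(cfg, seed = 7)
  expect_identical(a, b)
  c_ <- simulate_cohort(cfg, seed = 8)
  expect_false(identical(a$cells, c_$cells))
  expect_identical(nrow(a$patients), 3L)
  # every cell's ROI maps to a geometry and a patient
  expect_true(all(a$cells$roi_id %in% names(a$geometries)))
  expect_true(all(a$cells$patient_id %in% a$patients$patient_id))
  # per-patient ROI counts within the configured range
  rois_per_pat <- table(sub("_R[0-9]+$", "", names(a$geometries)))
  expect_true(all(rois_per_pat >= 2 & rois_per_pat <= 3))
})

test_that("degenerate configurations are handled: empty cohort, all-stroma ROI", {
  empty <- simulate_cohort(simulation_config(n_patients = 0), seed = 1)
  expect_identical(nrow(empty$patients), 0L)
  expect_identical(length(empty$geometries), 0L)
  roi <- simulate_roi("r1", "low", simulation_config(n_nests = 0), seed = 4)
  expect_identical(length(roi$geometry$tumour_polygons), 0L)
  expect_true(all(roi$cells$compartment == "stroma"))
})

test_that("configuration errors name the offending field", {
  expect_error(simulation_config(prop_pdl1_high = 1.5), "prop_pdl1_high",
               class = "tme_config_error")
  expect_error(simulation_config(cell_density = c(tumour = -5, stroma = 10)),
               "cell_density", class = "tme_config_error")
  expect_error(simulation_config(roi_width = 500, nest_radius_range = c(100, 400)),
               "nest_radius_range", class = "tme_config_error")
  bad_rates <- default_population_rates()
  bad_rates$high$tumour["CD4_T"] <- 0.9   # pushes the stratum sum over 1
  expect_error(simulation_config(population_rates = bad_rates),
               "population_rates", class = "tme_config_error")
})

test_that("PD-L1 group frequency falls in the binomial 99% interval", {
  pts <- simulate_patients(simulation_config(n_patients = 400,
                                             prop_pdl1_high = 0.25), seed = 9)
  n_high <- sum(pts$pdl1_group == "high")
  bounds <- qbinom(c(0.005, 0.995), 400, 0.25)
  expect_gte(n_high, bounds[1])
  expect_lte(n_high, bounds[2])
})

test_that("cell counts follow the configured Poisson intensity", {
  cfg <- simulation_config(n_nests = 0, roi_width = 1000, roi_height = 1000,
                           cell_density = c(tumour = 1000, stroma = 1000))
  roi <- simulate_roi("r", "low", cfg, seed = 15)
  bounds <- qpois(c(0.005, 0.995), 1000)
  expect_gte(nrow(roi$cells), bounds[1])
  expect_lte(nrow(roi$cells), bounds[2])
  # tumour-compartment intensity: three nests at known area
  cfg2 <- simulation_config(cell_density = c(tumour = 2000, stroma = 10))
  roi2 <- simulate_roi("r2", "high", cfg2, seed = 16)
  area <- sum(vapply(roi2$geometry$tumour_polygons, mifTME:::shoelace_area,
                     numeric(1))) * 1e-6
  n_t <- sum(roi2$cells$compartment == "tumour")
  b2 <- qpois(c(0.005, 0.995), 2000 * area)
  expect_gte(n_t, b2[1]); expect_lte(n_t, b2[2])
  # generator labels agree with the geometric compartment call
  comp_geo <- assign_compartment(roi2$cells$x_um, roi2$cells$y_um, roi2$geometry)
  expect_identical(comp_geo, roi2$cells$compartment)
})

test_that("survival draws obey the exponential model closed forms", {
  covars <- data.frame(pdl1_high = rep(0, 5000), met_bone = 0, ecog_1_2 = 0)
  model <- list(pfs = list(baseline_rate = 0.1,
                           log_hr = c(pdl1_high = 0, met_bone = 0, ecog_1_2 = 0)),
                os = list(baseline_rate = 0.05,
                          log_hr = c(pdl1_high = 0, met_bone = 0, ecog_1_2 = 0)),
                censoring_rate = 0)
  s <- simulate_survival(covars, model, seed = 20)
  expect_true(all(s$pfs_event == 1))
  expect_equal(median(s$pfs_months), log(2) / 0.1, tolerance = 0.05)
  # infinite censoring rate: everything censored at once
  model$censoring_rate <- Inf
  s2 <- simulate_survival(covars[1:50, ], model, seed = 21)
  expect_true(all(s2$pfs_event == 0))
  expect_true(all(s2$os_event == 0))
  # planted log-hazard ratios shift the linear predictor as configured
  covars2 <- data.frame(pdl1_high = c(0, 1), met_bone = c(1, 0), ecog_1_2 = 0)
  s3 <- simulate_survival(covars2, default_survival_model(), seed = 22)
  expect_equal(s3$lp_pfs, c(log(2.123), log(2.792)))
})

test_that("patient substreams are stable under cohort-size edits", {
  small <- simulate_patients(simulation_config(n_patients = 3), seed = 40)
  large <- simulate_patients(simulation_config(n_patients = 6), seed = 40)
  # covariates of the first three patients are unchanged when the cohort grows
  covar_cols <- setdiff(names(small), c("pfs_months", "pfs_event",
                                        "os_months", "os_event",
                                        "lp_pfs", "lp_os"))
  expect_identical(small[covar_cols], large[1:3, covar_cols])
})
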