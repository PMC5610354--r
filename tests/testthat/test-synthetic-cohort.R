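test_that("config validation rejects impossible configurations", {
  expect_error(cohort_config(age_band_weights = rep(0, 5)),
               class = "telebaci_config_error")
  expect_error(cohort_config(age_band_weights = c(0.5, 0.5, 0.1, 0, 0)),
               class = "telebaci_config_error")
  expect_error(cohort_config(male_fraction = 1.2),
               class = "telebaci_config_error")
  expect_error(cohort_config(days_before = -30),
               class = "telebaci_config_error")
  expect_error(cohort_config(controls_per_test = 5),
               class = "telebaci_config_error")
})

test_that("noiseless, delta-free cohorts put every sqrt bin total on the line", {
  cfg <- cohort_config(n_test = 6, controls_per_test = 1,
                       cost_noise_sd = 0, post_slope_delta_test = 0,
                       post_slope_delta_control = 0,
                       asdr_per_band = rep(0, 5), seed = 4)
  coh <- generate_cohort(cfg)
  binned <- bin_events(coh$claims, coh$patients, 30, 36, 12, value = "cost")
  expected <- cfg$baseline_sqrt_cost + cfg$pre_slope_sqrt * (binned$bin + 36)
  expect_equal(sqrt(binned$total), expected, tolerance = 1e-8)
})

test_that("zero death rates yield no deaths; events never postdate a death", {
  coh0 <- generate_cohort(small_config(asdr_per_band = rep(0, 5)))
  expect_true(all(is.na(coh0$patients$death_day)))

  coh <- generate_cohort(cohort_config(n_test = 40, seed = 9,
                                       asdr_per_band = rep(0.5, 5)))
  expect_gt(sum(!is.na(coh$patients$death_day)), 0)
  dd <- coh$patients$death_day[match(coh$claims$patient_id,
                                     coh$patients$patient_id)]
  expect_true(all(is.na(dd) | coh$claims$day <= dd))
  dda <- coh$patients$death_day[match(coh$admissions$patient_id,
                                      coh$patients$patient_id)]
  expect_true(all(is.na(dda) | coh$admissions$admit_day <= dda))
  expect_true(all(coh$claims$cost >= 0))
  expect_true(all(coh$admissions$los[coh$admissions$overnight] >= 1))
})

test_that("controls match their test partner exactly on the matching variables", {
  coh <- generate_cohort(small_config())
  p <- coh$patients
  ctrl <- p[p$arm == "control", ]
  partner <- p[match(ctrl$matched_to, p$patient_id), ]
  expect_equal(ctrl$gender, partner$gender)
  expect_equal(ctrl$diagnosis_group, partner$diagnosis_group)
  expect_equal(ctrl$seifa, partner$seifa)
  expect_equal(ctrl$band_idx, partner$band_idx)
  expect_equal(ctrl$intervention_date, partner$intervention_date)
  expect_true(all(p$age_at_intervention >= 50))
})

test_that("identical seeds give byte-identical cohorts, different seeds differ", {
  a <- generate_cohort(cohort_config(n_test = 10, seed = 21))
  b <- generate_cohort(cohort_config(n_test = 10, seed = 21))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  d <- generate_cohort(cohort_config(n_test = 10, seed = 22))
  expect_false(identical(a$claims, d$claims))

  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  write_cohort(a, dir_a)
  write_cohort(b, dir_b)
  for (f in c("patients.csv", "claims.csv", "admissions.csv")) {
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)))
  }
  back <- read_cohort(dir_a)
  expect_equal(nrow(back$claims), nrow(a$claims))
  expect_equal(back$config$seed, a$config$seed)
})

test_that("binned sqrt-cost means converge to the configured line (n = 1000)", {
  cfg <- cohort_config(n_test = 500, controls_per_test = 1,
                       cost_noise_sd = 0.5, post_slope_delta_test = 0,
                       post_slope_delta_control = 0,
                       asdr_per_band = rep(0, 5), seed = 2024)
  coh <- generate_cohort(cfg)
  binned <- bin_events(coh$claims, coh$patients, 30, 36, 12, value = "cost")
  series <- transform_series(average_patients(binned, 30), "sqrt")
  fit <- fit_segment(series, "pooled", exclude = FALSE)
  se <- fit$rmse / sqrt(fit$sxx)
  expect_lt(abs(fit$slope - cfg$pre_slope_sqrt), 3 * se)
  # intercept at bin -36 is the configured baseline
  expect_lt(abs((fit$intercept - 36 * fit$slope) - cfg$baseline_sqrt_cost), 0.1)
})

test_that("death fractions per age band converge to the configured hazard (n = 2000)", {
  p_band <- 0.15
  cfg <- cohort_config(n_test = 1000, controls_per_test = 1,
                       age_band_weights = c(1, 0, 0, 0, 0),
                       asdr_per_band = c(p_band, 0, 0, 0, 0),
                       claims_per_bin = 1, seed = 77)
  coh <- generate_cohort(cfg)
  n <- nrow(coh$patients)
  window_years <- (cfg$days_before + cfg$days_after) / 365
  p_window <- 1 - (1 - p_band)^window_years
  frac <- mean(!is.na(coh$patients$death_day))
  se <- sqrt(p_window * (1 - p_window) / n)
  expect_lt(abs(frac - p_window), 3 * se)
})
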