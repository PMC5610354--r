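#' Configuration for the synthetic matched-cohort generator
#'
#' Parameterises the statistical structure the BACI analysis assumes: per-arm
#' cost streams whose square-root 30-day bin means drift linearly (with a slope
#' change at intervention), sparse overdispersed hospital admissions with
#' per-admission length of stay, and age-band-specific mortality applied as a
#' constant hazard over the observation window.
#'
#' Defaults describe a trial-scale cohort of chronically ill patients aged 50+:
#' 100 test patients with 2 matched controls each, a medical-expenditure
#' trajectory whose pre-intervention projection reaches roughly $2800/year one
#' year after the start of monitoring, a test-arm post-intervention slope half
#' the pre-intervention slope, and register mortality rates by 10-year age band
#' from 50 to 100.
#'
#' @param n_test number of test (telemonitored) patients.
#' @param controls_per_test matched controls generated per test patient (1-4).
#' @param age_band_weights probabilities over the five 10-year age bands
#'   50-60, ..., 90-100; must sum to 1.
#' @param male_fraction proportion of male patients.
#' @param diagnosis_weights probabilities over diagnosis groups
#'   (cardiovascular, respiratory, diabetes); must sum to 1.
#' @param seifa_levels number of ordinal socioeconomic (SEIFA) levels.
#' @param baseline_sqrt_cost sqrt(AUD) per 30-day bin at 3 years before
#'   intervention.
#' @param pre_slope_sqrt drift of sqrt(30-day cost) per 30-day bin before
#'   intervention (sqrt(AUD) per bin).
#' @param post_slope_delta_test additive change to that drift at intervention,
#'   test arm.
#' @param post_slope_delta_control same for the control arm (default 0: usual
#'   care continues on its trajectory).
#' @param cost_noise_sd per-patient, per-bin noise on the sqrt scale.
#' @param claims_per_bin mean number of claim events per 30-day bin used to
#'   split a bin's total into dated claims.
#' @param admission_rate_per_100d mean overnight admissions per 100-day bin
#'   before intervention.
#' @param admission_post_mult_test,admission_post_mult_control multiplier on
#'   the admission rate from intervention onward, per arm.
#' @param admission_dispersion negative-binomial size parameter for per-bin
#'   admission counts (smaller = more overdispersed).
#' @param los_mean_days mean length of stay per overnight admission, days.
#' @param los_post_mult_test,los_post_mult_control multiplier on mean LOS from
#'   intervention onward, per arm.
#' @param nonovernight_fraction fraction of hospital attendances that involve
#'   no overnight stay (emergency-department visits; excluded from analysis).
#' @param asdr_per_band annual death probability per age band.
#' @param days_before,days_after observation horizons around intervention, days.
#' @param seed RNG seed; identical seeds give byte-identical cohorts.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_test = 100,
                          controls_per_test = 2,
                          age_band_weights = c(0.41, 0.31, 0.14, 0.13, 0.01),
                          male_fraction = 0.67,
                          diagnosis_weights = c(cardiovascular = 0.5,
                                                respiratory = 0.3,
                                                diabetes = 0.2),
                          seifa_levels = 5,
                          baseline_sqrt_cost = 9,
                          pre_slope_sqrt = 0.13,
                          post_slope_delta_test = -0.065,
                          post_slope_delta_control = 0,
                          cost_noise_sd = 1,
                          claims_per_bin = 3,
                          admission_rate_per_100d = 0.9,
                          admission_post_mult_test = 0.5,
                          admission_post_mult_control = 1,
                          admission_dispersion = 4,
                          los_mean_days = 6,
                          los_post_mult_test = 0.4,
                          los_post_mult_control = 1,
                          nonovernight_fraction = 0.1,
                          asdr_per_band = c(0.0944, 0.1484, 0.1361,
                                            0.2198, 0.4405),
                          days_before = 1080,
                          days_after = 360,
                          seed = 1L) {
  if (!is.numeric(n_test) || n_test < 1) {
    abort_telebaci("`n_test` must be a positive count", "telebaci_config_error")
  }
  if (!controls_per_test %in% 1:4) {
    abort_telebaci("`controls_per_test` must be in 1..4", "telebaci_config_error")
  }
  if (length(age_band_weights) != 5) {
    abort_telebaci("`age_band_weights` needs one weight per 10-year band 50-100",
                   "telebaci_config_error")
  }
  check_weights(age_band_weights, "age_band_weights")
  check_prob(male_fraction, "male_fraction")
  check_weights(diagnosis_weights, "diagnosis_weights")
  if (length(asdr_per_band) != 5) {
    abort_telebaci("`asdr_per_band` needs one rate per 10-year band 50-100",
                   "telebaci_config_error")
  }
  check_prob(asdr_per_band, "asdr_per_band")
  check_prob(nonovernight_fraction, "nonovernight_fraction")
  if (days_before <= 0 || days_after <= 0) {
    abort_telebaci("horizons must be positive", "telebaci_config_error")
  }
  if (baseline_sqrt_cost < 0) {
    abort_telebaci("`baseline_sqrt_cost` must be >= 0", "telebaci_config_error")
  }
  if (cost_noise_sd < 0 || claims_per_bin <= 0 || los_mean_days < 1 ||
      admission_rate_per_100d < 0 || admission_dispersion <= 0 ||
      seifa_levels < 1) {
    abort_telebaci("invalid rate/noise/level parameter", "telebaci_config_error")
  }

  if (is.null(names(diagnosis_weights))) {
    names(diagnosis_weights) <- c("cardiovascular", "respiratory", "diabetes")
  }
  cfg <- list(
    n_test = as.integer(n_test),
    controls_per_test = as.integer(controls_per_test),
    age_band_weights = age_band_weights,
    male_fraction = male_fraction,
    diagnosis_weights = diagnosis_weights,
    seifa_levels = as.integer(seifa_levels),
    baseline_sqrt_cost = baseline_sqrt_cost,
    pre_slope_sqrt = pre_slope_sqrt,
    post_slope_delta_test = post_slope_delta_test,
    post_slope_delta_control = post_slope_delta_control,
    cost_noise_sd = cost_noise_sd,
    claims_per_bin = claims_per_bin,
    admission_rate_per_100d = admission_rate_per_100d,
    admission_post_mult_test = admission_post_mult_test,
    admission_post_mult_control = admission_post_mult_control,
    admission_dispersion = admission_dispersion,
    los_mean_days = los_mean_days,
    los_post_mult_test = los_post_mult_test,
    los_post_mult_control = los_post_mult_control,
    nonovernight_fraction = nonovernight_fraction,
    asdr_per_band = asdr_per_band,
    days_before = as.integer(days_before),
    days_after = as.integer(days_after),
    seed = as.integer(seed)
  )
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d test patients x %d controls; window -%d..+%d days\n",
              x$n_test, x$controls_per_test, x$days_before, x$days_after))
  cat(sprintf("  sqrt-cost line: %.3g + %.3g*(bin+%d); post delta test %.3g, control %.3g\n",
              x$baseline_sqrt_cost, x$pre_slope_sqrt, x$days_before %/% 30L,
              x$post_slope_delta_test, x$post_slope_delta_control))
  cat(sprintf("  admissions %.2g / 100d (post mult %.2g test, %.2g control); LOS mean %.2g d\n",
              x$admission_rate_per_100d, x$admission_post_mult_test,
              x$admission_post_mult_control, x$los_mean_days))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

age_bands <- function() {
  tibble::tibble(
    band = c("50-60", "60-70", "70-80", "80-90", "90-100"),
    lo = c(50, 60, 70, 80, 90),
    hi = c(60, 70, 80, 90, 100)
  )
}
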