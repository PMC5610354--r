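#' Generate a synthetic matched telemonitoring cohort
#'
#' Simulates test and control patients with claim, admission and death
#' histories carrying the structure the downstream BACI analysis assumes:
#'
#' * the expected total cost of a patient in 30-day bin `t`
#'   (`t = -days_before/30 .. days_after/30 - 1`) is
#'   `(baseline_sqrt_cost + pre_slope_sqrt * (t + n_before) + delta * max(t, 0))^2`
#'   with `delta` the arm's post-intervention slope change; per-patient noise is
#'   normal on the sqrt scale, and a bin's total is split into Poisson-many
#'   gamma-share claim events dated uniformly within the bin;
#' * overnight admissions are overdispersed (negative-binomial) counts per
#'   100-day bin with per-admission length of stay, plus a fraction of
#'   non-overnight emergency-department attendances that the analysis excludes;
#' * death is a constant within-age-band hazard over the whole observation
#'   window, calibrated so the annual death probability equals `asdr_per_band`;
#'   a death truncates the patient's event streams.
#'
#' Controls are generated as exact demographic matches (gender, diagnosis
#' group, SEIFA, age band) of their test partner and inherit its intervention
#' date as time anchor, so all event days are signed offsets from day 0, the
#' first monitored day.
#'
#' @param config a [cohort_config()].
#' @return an object of class `telebaci_cohort`: a list with tibbles
#'   `patients` (patient_id, arm, matched_to, age_at_intervention, gender,
#'   diagnosis_group, seifa, intervention_date, death_day), `claims`
#'   (patient_id, day, category, cost), `admissions` (patient_id, admit_day,
#'   los, overnight), and the `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_test = 5, seed = 7))
#' coh$patients
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort_telebaci("`config` must be a cohort_config", "telebaci_config_error")
  }
  set.seed(config$seed)
  patients <- draw_patients(config)
  patients$death_day <- draw_deaths(patients, config)
  claims <- draw_claims(patients, config)
  admissions <- draw_admissions(patients, config)
  structure(list(patients = patients, claims = claims,
                 admissions = admissions, config = config),
            class = "telebaci_cohort")
}

#' @export
print.telebaci_cohort <- function(x, ...) {
  cat(sprintf("<telebaci_cohort> %d patients (%d test), %d claims, %d admissions, %d deaths\n",
              nrow(x$patients), sum(x$patients$arm == "test"),
              nrow(x$claims), nrow(x$admissions),
              sum(!is.na(x$patients$death_day))))
  invisible(x)
}

draw_patients <- function(cfg) {
  bands <- age_bands()
  n_t <- cfg$n_test
  k <- cfg$controls_per_test

  band_idx <- sample.int(5L, n_t, replace = TRUE, prob = cfg$age_band_weights)
  test <- tibble::tibble(
    patient_id = sprintf("T%04d", seq_len(n_t)),
    arm = "test",
    matched_to = NA_character_,
    band_idx = band_idx,
    age_at_intervention = bands$lo[band_idx] + stats::runif(n_t, 0, 10),
    gender = ifelse(stats::rbinom(n_t, 1, cfg$male_fraction) == 1, "M", "F"),
    diagnosis_group = sample(names(cfg$diagnosis_weights), n_t,
                             replace = TRUE, prob = cfg$diagnosis_weights),
    seifa = sample.int(cfg$seifa_levels, n_t, replace = TRUE),
    intervention_date = sample.int(540L, n_t, replace = TRUE)
  )

  # controls clone the matching variables of their test partner and share its
  # anchor date; age re-drawn within the same 10-year band
  ctrl <- test[rep(seq_len(n_t), each = k), ]
  ctrl$matched_to <- ctrl$patient_id
  ctrl$patient_id <- sprintf("C%04d", seq_len(n_t * k))
  ctrl$arm <- "control"
  ctrl$age_at_intervention <-
    bands$lo[ctrl$band_idx] + stats::runif(n_t * k, 0, 10)

  dplyr::bind_rows(test, ctrl)
}

draw_deaths <- function(patients, cfg) {
  window <- cfg$days_before + cfg$days_after
  p_annual <- cfg$asdr_per_band[patients$band_idx]
  hazard <- -log(1 - p_annual) / 365
  t_death <- rep(Inf, nrow(patients))
  pos <- hazard > 0
  t_death[pos] <- stats::rexp(sum(pos), rate = hazard[pos])
  ifelse(t_death < window,
         as.integer(floor(t_death)) - cfg$days_before,
         NA_integer_)
}

sqrt_mean_line <- function(bin, arm, cfg) {
  n_before <- cfg$days_before %/% 30L
  delta <- ifelse(arm == "test",
                  cfg$post_slope_delta_test, cfg$post_slope_delta_control)
  cfg$baseline_sqrt_cost + cfg$pre_slope_sqrt * (bin + n_before) +
    delta * pmax(bin, 0)
}

draw_claims <- function(patients, cfg) {
  n_before <- cfg$days_before %/% 30L
  n_after <- cfg$days_after %/% 30L
  bins <- seq.int(-n_before, n_after - 1L)

  grid <- tidyr::expand_grid(
    patient_id = patients$patient_id,
    bin = bins
  )
  grid$arm <- patients$arm[match(grid$patient_id, patients$patient_id)]
  grid$death_day <- patients$death_day[match(grid$patient_id,
                                             patients$patient_id)]
  m <- sqrt_mean_line(grid$bin, grid$arm, cfg)
  s <- m + stats::rnorm(nrow(grid), 0, cfg$cost_noise_sd)
  target <- pmax(s, 0)^2

  n_events <- ifelse(target > 0,
                     pmax(1L, stats::rpois(nrow(grid), cfg$claims_per_bin)),
                     0L)
  keep <- n_events > 0L
  grid <- grid[keep, ]
  target <- target[keep]
  n_events <- n_events[keep]

  idx <- rep.int(seq_along(n_events), n_events)
  n_total <- length(idx)
  shares <- stats::rgamma(n_total, shape = 1)
  denom <- rowsum(shares, idx)[, 1L]
  cost <- target[idx] * shares / denom[idx]
  day <- grid$bin[idx] * 30L + as.integer(floor(stats::runif(n_total, 0, 30)))
  category <- ifelse(stats::rbinom(n_total, 1, 0.5) == 1,
                     "medical", "pharmaceutical")

  claims <- tibble::tibble(
    patient_id = grid$patient_id[idx],
    day = day,
    category = category,
    cost = cost
  )
  dd <- grid$death_day[idx]
  claims <- claims[is.na(dd) | claims$day <= dd, ]
  claims[order(claims$patient_id, claims$day), ]
}

draw_admissions <- function(patients, cfg) {
  n_before <- as.integer(ceiling(cfg$days_before / 100))
  n_after <- as.integer(ceiling(cfg$days_after / 100))
  bins <- seq.int(-n_before, n_after - 1L)

  grid <- tidyr::expand_grid(patient_id = patients$patient_id, bin = bins)
  pi <- match(grid$patient_id, patients$patient_id)
  grid$arm <- patients$arm[pi]
  grid$death_day <- patients$death_day[pi]

  # partial edge bins (horizon not a multiple of 100 d) carry prorated rates
  lo <- pmax(grid$bin * 100L, -cfg$days_before)
  hi <- pmin((grid$bin + 1L) * 100L, cfg$days_after)
  coverage <- (hi - lo) / 100

  mult <- ifelse(grid$bin >= 0L,
                 ifelse(grid$arm == "test",
                        cfg$admission_post_mult_test,
                        cfg$admission_post_mult_control),
                 1)
  mu <- cfg$admission_rate_per_100d * mult * coverage
  counts <- stats::rnbinom(nrow(grid), mu = mu, size = cfg$admission_dispersion)

  keep <- counts > 0L
  grid <- grid[keep, ]; lo <- lo[keep]; hi <- hi[keep]
  counts <- counts[keep]
  idx <- rep.int(seq_along(counts), counts)
  n_total <- length(idx)
  admit_day <- lo[idx] +
    as.integer(floor(stats::runif(n_total) * (hi[idx] - lo[idx])))

  los_mult <- ifelse(admit_day >= 0L,
                     ifelse(grid$arm[idx] == "test",
                            cfg$los_post_mult_test, cfg$los_post_mult_control),
                     1)
  overnight <- stats::rbinom(n_total, 1, 1 - cfg$nonovernight_fraction) == 1
  los <- ifelse(overnight,
                1L + stats::rpois(n_total,
                                  pmax(cfg$los_mean_days * los_mult - 1, 0)),
                0L)

  adm <- tibble::tibble(
    patient_id = grid$patient_id[idx],
    admit_day = admit_day,
    los = as.integer(los),
    overnight = overnight
  )
  dd <- grid$death_day[idx]
  adm <- adm[is.na(dd) | adm$admit_day <= dd, ]
  adm[order(adm$patient_id, adm$admit_day), ]
}

#' Write / read a cohort as plain CSV plus a JSON config sidecar
#'
#' `write_cohort()` writes `patients.csv`, `claims.csv`, `admissions.csv` and
#' `config.json` into `dir`; `read_cohort()` reads them back. Dates are stored
#' as signed integer day offsets from each patient's intervention anchor.
#'
#' @param cohort a `telebaci_cohort`.
#' @param dir output (input) directory; created if missing.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `telebaci_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$claims, file.path(dir, "claims.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$admissions, file.path(dir, "admissions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pat <- tibble::as_tibble(utils::read.csv(file.path(dir, "patients.csv")))
  pat$death_day <- as.integer(pat$death_day)
  cl <- tibble::as_tibble(utils::read.csv(file.path(dir, "claims.csv")))
  adm <- tibble::as_tibble(utils::read.csv(file.path(dir, "admissions.csv")))
  cfg_path <- file.path(dir, "config.json")
  cfg <- NULL
  if (file.exists(cfg_path)) {
    cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    cfg$diagnosis_weights <- unlist(cfg$diagnosis_weights)
    cfg <- do.call(cohort_config, cfg[names(cfg) %in%
                                        names(formals(cohort_config))])
  }
  structure(list(patients = pat, claims = cl, admissions = adm, config = cfg),
            class = "telebaci_cohort")
}
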