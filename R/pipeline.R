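#' Configuration for the end-to-end BACI analysis
#'
#' @param cohort a [cohort_config()] for the simulator, or `NULL` when reading
#'   an existing cohort from `input_dir`.
#' @param input_dir directory with patients.csv / claims.csv / admissions.csv
#'   (see [write_cohort()]); `NULL` to simulate.
#' @param outcomes outcomes to analyse, a subset of `total_cost`,
#'   `medical_cost`, `pharma_cost`, `admissions`, `los`.
#' @param alpha two-tailed significance level.
#' @param register,cohort_table optional mortality inputs (band, pop, deaths /
#'   band, n, observed_deaths); by default the register is derived from the
#'   full simulated cohort and the cohort table from its test arm.
#' @param out_dir directory for report files; `NULL` = return only.
#' @param seed seed for every stochastic step (overrides the cohort config's).
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(cohort = cohort_config(),
                            input_dir = NULL,
                            outcomes = c("total_cost", "medical_cost",
                                         "pharma_cost", "admissions", "los"),
                            alpha = 0.05,
                            register = NULL,
                            cohort_table = NULL,
                            out_dir = NULL,
                            seed = 1L) {
  allowed <- c("total_cost", "medical_cost", "pharma_cost",
               "admissions", "los")
  if (!all(outcomes %in% allowed)) {
    abort_telebaci(sprintf("outcomes must be a subset of {%s}",
                           paste(allowed, collapse = ", ")),
                   "telebaci_config_error")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort_telebaci("`alpha` must be in (0, 1)", "telebaci_config_error")
  }
  structure(list(cohort = cohort, input_dir = input_dir, outcomes = outcomes,
                 alpha = alpha, register = register,
                 cohort_table = cohort_table, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

outcome_binning <- function(outcome, cohort) {
  cfg <- cohort$config
  days_before <- if (is.null(cfg)) 1080L else cfg$days_before
  days_after <- if (is.null(cfg)) 360L else cfg$days_after
  if (outcome %in% c("total_cost", "medical_cost", "pharma_cost")) {
    events <- cohort$claims
    if (outcome == "medical_cost") events <- events[events$category == "medical", ]
    if (outcome == "pharma_cost") {
      events <- events[events$category == "pharmaceutical", ]
    }
    list(events = events, value = "cost", width = 30L,
         n_before = days_before %/% 30L, n_after = days_after %/% 30L,
         forced_transform = "sqrt")
  } else {
    events <- cohort$admissions[cohort$admissions$overnight, ]
    events$day <- events$admit_day
    list(events = events, value = if (outcome == "los") "los" else NULL,
         width = 100L,
         n_before = as.integer(ceiling(days_before / 100)),
         n_after = as.integer(ceiling(days_after / 100)),
         forced_transform = NULL)
  }
}

# per-arm averaged series: test arm = plain cross-patient mean; control arm =
# mean over effective (within-pair averaged) controls
arm_series <- function(binned, patients, pairs, width, outcome) {
  test_ids <- patients$patient_id[patients$arm == "test"]
  test_series <- average_patients(binned[binned$patient_id %in% test_ids, ],
                                  width, outcome)
  eff <- lapply(seq_len(nrow(pairs)), function(i) {
    if (pairs$n_controls[i] == 0) return(NULL)
    ids <- strsplit(pairs$control_ids[i], ";", fixed = TRUE)[[1]]
    series_list <- lapply(ids, function(id) {
      b <- binned[binned$patient_id == id, ]
      tibble::tibble(bin = b$bin, total = b$total, observed = b$observed)
    })
    avg <- average_controls(series_list)
    avg$patient_id <- pairs$test_id[i]
    avg
  })
  eff <- dplyr::bind_rows(eff[!vapply(eff, is.null, logical(1))])
  eff$total[!eff$observed] <- 0  # unobserved bins carry no value; flag governs
  control_series <- average_patients(eff, width, outcome)
  list(test = test_series, control = control_series)
}

analyze_outcome <- function(outcome, cohort, pairs, alpha) {
  spec <- outcome_binning(outcome, cohort)
  binned <- bin_events(spec$events, cohort$patients, spec$width,
                       spec$n_before, spec$n_after, value = spec$value)
  ser <- arm_series(binned, cohort$patients, pairs, spec$width, outcome)

  per_arm <- lapply(ser, function(s) {
    sel <- select_transform(s, alpha = alpha)
    transform <- spec$forced_transform %||% sel$transform
    if (transform == "log") transform <- sel$transform  # rate curves need sqrt/identity
    ts <- transform_series(s, transform)
    cmp <- compare_slopes(ts)
    before_curve <- annualize(cmp$fit_before)
    after_curve <- annualize(cmp$fit_after)
    savings <- tryCatch(estimate_savings(before_curve, after_curve),
                        telebaci_savings_error = function(e) NULL)
    list(series = ts, transform = transform,
         normality_p = as.list(sel$p_values),
         comparison = cmp, savings = savings)
  })

  diff <- difference_series(ser$control, ser$test)
  diff_cmp <- compare_slopes(diff)
  diff_savings <- tryCatch(
    estimate_savings(annualize(diff_cmp$fit_before),
                     annualize(diff_cmp$fit_after)),
    telebaci_savings_error = function(e) NULL)

  list(test = per_arm$test, control = per_arm$control,
       difference = list(series = diff, comparison = diff_cmp,
                         savings = diff_savings))
}

segment_fit_to_list <- function(fit) {
  list(intercept = fit$intercept, slope = fit$slope, n = fit$n,
       sse = fit$sse, r2 = fit$r2, adj_r2 = fit$adj_r2, rmse = fit$rmse,
       excluded_outliers = as.list(fit$excluded_outliers))
}

comparison_to_list <- function(cmp) {
  list(fit_before = segment_fit_to_list(cmp$fit_before),
       fit_after = segment_fit_to_list(cmp$fit_after),
       common_fit = segment_fit_to_list(cmp$common_fit),
       interaction_estimate = cmp$interaction_estimate,
       p_interaction = cmp$p_interaction,
       p_partial_f = cmp$p_partial_f,
       p_common_vs_before = cmp$p_common_vs_before)
}

savings_to_list <- function(sv) {
  if (is.null(sv)) return(NULL)
  list(projected_annual_total = sv$projected_annual_total,
       actual_annual_total = sv$actual_annual_total,
       saving = sv$saving, saving_pct = sv$saving_pct,
       rate_reduction_pct = sv$rate_reduction_pct,
       intersection_day = if (is.na(sv$intersection_day)) NULL
                          else sv$intersection_day,
       start_day = sv$start_day, unit = sv$unit)
}

baseline_section <- function(cohort, pairs, alpha) {
  patients <- cohort$patients
  cfg <- cohort$config
  days_after <- if (is.null(cfg)) 360L else cfg$days_after
  patients$end_day <- pmin(days_after,
                           ifelse(is.na(patients$death_day), days_after,
                                  patients$death_day + 1L))
  out <- list()
  for (w in c("pre_start", "pre_end")) {
    ws <- window_sum(cohort$claims, patients, window = w)
    ws$arm <- patients$arm[match(ws$patient_id, patients$patient_id)]
    test_tot <- stats::setNames(ws$total[ws$arm == "test"],
                                ws$patient_id[ws$arm == "test"])
    ctrl_eff <- vapply(seq_len(nrow(pairs)), function(i) {
      if (pairs$n_controls[i] == 0) return(NA_real_)
      ids <- strsplit(pairs$control_ids[i], ";", fixed = TRUE)[[1]]
      mean(ws$total[match(ids, ws$patient_id)], na.rm = TRUE)
    }, numeric(1))
    paired <- test_tot[pairs$test_id]
    ok <- !is.na(paired) & !is.na(ctrl_eff)
    cmp <- paired_compare(unname(paired[ok]), ctrl_eff[ok])
    out[[w]] <- list(
      test = summarize_window(unname(paired[ok])),
      control = summarize_window(ctrl_eff[ok]),
      paired = cmp,
      annualized_difference = annualized_group_difference(
        mean(ctrl_eff[ok]), mean(paired[ok], na.rm = TRUE))
    )
  }
  out$age_p <- group_compare(patients$age_at_intervention, patients$arm)$p_value
  out$gender_p <- group_compare(patients$gender, patients$arm)$p_value
  out
}

mortality_section <- function(cohort, register, cohort_table) {
  if (is.null(register)) {
    bands <- age_bands()
    bi <- findInterval(cohort$patients$age_at_intervention,
                       c(bands$lo, 100), rightmost.closed = TRUE)
    bi <- pmin(pmax(bi, 1L), 5L)
    died <- !is.na(cohort$patients$death_day)
    register <- tibble::tibble(
      band = bands$band,
      pop = as.integer(tabulate(bi, 5)),
      deaths = as.integer(tabulate(bi[died], 5)))
    is_test <- cohort$patients$arm == "test"
    cohort_table <- tibble::tibble(
      band = bands$band,
      n = as.integer(tabulate(bi[is_test], 5)),
      observed_deaths = as.integer(tabulate(bi[is_test & died], 5)))
    register <- register[register$pop > 0, ]
    cohort_table <- cohort_table[cohort_table$band %in% register$band, ]
  }
  m <- mortality_analysis(register, cohort_table)
  list(
    asdr = as.list(stats::setNames(m$asdr$asdr, m$asdr$band)),
    crude_rate_register = m$crude_rate_register,
    observed = m$observed,
    expected_total = m$expected_total,
    expected_total_printed = m$expected_total_printed,
    deaths_saved = m$expected_total - m$observed,
    reduction_pct = m$reduction_pct
  )
}

#' Run the full BACI pipeline
#'
#' Orchestrates simulate (or load) -> match -> bin/average -> segmented
#' regression with slope ANCOVA -> annualised savings -> baseline window
#' comparisons -> mortality standardisation, and assembles a machine-readable
#' report. Every stochastic step is seeded from `config$seed`, so identical
#' configurations give identical reports. With `out_dir` set, the report is
#' written as `report.json` alongside `binned.csv` and `pairs.csv`.
#'
#' @param config an [analysis_config()].
#' @return the report, a nested list (class `telebaci_report`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "analysis_config")) {
    abort_telebaci("`config` must be an analysis_config",
                   "telebaci_config_error")
  }
  cohort <- if (!is.null(config$input_dir)) {
    read_cohort(config$input_dir)
  } else {
    cc <- config$cohort
    cc$seed <- config$seed
    generate_cohort(cc)
  }

  tests <- cohort$patients[cohort$patients$arm == "test", ]
  pool <- cohort$patients[cohort$patients$arm == "control", ]
  k_max <- if (!is.null(cohort$config)) cohort$config$controls_per_test else 2L
  pairs <- suppressWarnings(match_controls(tests, pool, k_max = k_max))

  outcomes <- lapply(stats::setNames(config$outcomes, config$outcomes),
                     function(oc) {
    res <- analyze_outcome(oc, cohort, pairs, config$alpha)
    lapply(res, function(armres) {
      out <- list(comparison = comparison_to_list(armres$comparison),
                  savings = savings_to_list(armres$savings))
      if (!is.null(armres$transform)) out$transform <- armres$transform
      if (!is.null(armres$normality_p)) out$normality_p <- armres$normality_p
      out
    })
  })

  report <- list(
    package = "telebaci",
    seed = config$seed,
    alpha = config$alpha,
    n_test = nrow(tests),
    n_control = nrow(pool),
    matching = list(n_pairs = sum(pairs$n_controls > 0),
                    n_unmatched = length(attr(pairs, "unmatched")),
                    mean_distance = mean(pairs$match_distance, na.rm = TRUE)),
    outcomes = outcomes,
    baseline = baseline_section(cohort, pairs, config$alpha),
    mortality = mortality_section(cohort, config$register,
                                  config$cohort_table)
  )
  class(report) <- c("telebaci_report", "list")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
    write_pairs(pairs, file.path(config$out_dir, "pairs.csv"))
  }
  report
}

#' @export
print.telebaci_report <- function(x, ...) {
  cat("<telebaci_report>\n")
  cat(sprintf("  %d test / %d control patients; %d matched pairs\n",
              x$n_test, x$n_control, x$matching$n_pairs))
  for (oc in names(x$outcomes)) {
    t <- x$outcomes[[oc]]$test
    rr <- t$savings$rate_reduction_pct
    cat(sprintf("  %-12s test slope change p = %.3g%s\n", oc,
                t$comparison$p_interaction,
                if (!is.null(rr)) sprintf("; rate reduction at 1 y %.1f%%", rr)
                else ""))
  }
  cat(sprintf("  mortality: observed %g vs expected %.2f (reduction %.1f%%)\n",
              x$mortality$observed, x$mortality$expected_total,
              x$mortality$reduction_pct))
  invisible(x)
}

#' Check a report against the shipped schema
#'
#' A minimal structural validator (required keys and scalar types) against the
#' JSON schema at `inst/schema/report-schema.json`. Returns `TRUE` invisibly
#' or raises an error naming the first missing key.
#'
#' @param report a `telebaci_report` (or a list parsed from report.json).
#' @return `TRUE`, invisibly.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(
    system.file("schema", "report-schema.json", package = "telebaci"))
  check_required <- function(obj, sch, path = "") {
    req <- unlist(sch$required)
    for (key in req) {
      if (is.null(obj[[key]])) {
        abort_telebaci(sprintf("report is missing required key %s%s",
                               path, key), "telebaci_report_error")
      }
      sub <- sch$properties[[key]]
      if (!is.null(sub$required)) {
        check_required(obj[[key]], sub, paste0(path, key, "."))
      }
    }
  }
  check_required(report, schema)
  invisible(TRUE)
}
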