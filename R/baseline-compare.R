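#' Per-patient expenditure totals over a 100-day window
#'
#' Sums each patient's costs over a half-open 100-day window: the last 100
#' days before the start of intervention (`[-window_days, 0)`), or the last
#' 100 days before each patient's own end of monitoring
#' (`[end_day - window_days, end_day)`). Patients dead before the window
#' starts are flagged and excluded from the totals (recorded in the `excluded`
#' attribute), never summed as zeros.
#'
#' @param events tibble with `patient_id`, `day`, `cost`.
#' @param patients tibble with `patient_id`, `death_day`, and for the
#'   `pre_end` window an `end_day` column (each patient's last monitored day,
#'   exclusive).
#' @param window `"pre_start"` or `"pre_end"`.
#' @param window_days window length in days (100).
#' @return tibble (patient_id, total, excluded) with attribute `excluded`
#'   listing flagged patient ids.
#' @export
window_sum <- function(events, patients, window = c("pre_start", "pre_end"),
                       window_days = 100) {
  window <- match.arg(window)
  if (window == "pre_end" && !"end_day" %in% names(patients)) {
    abort_telebaci("`patients` needs an `end_day` column for the pre_end window",
                   "telebaci_baseline_error")
  }
  lo <- switch(window,
               pre_start = rep(-window_days, nrow(patients)),
               pre_end = patients$end_day - window_days)
  hi <- switch(window,
               pre_start = rep(0, nrow(patients)),
               pre_end = patients$end_day)
  names(lo) <- names(hi) <- patients$patient_id

  dead_before <- !is.na(patients$death_day) & patients$death_day < lo
  idx <- match(events$patient_id, patients$patient_id)
  keep <- !is.na(idx) & events$day >= lo[idx] & events$day < hi[idx]
  tot <- if (any(keep)) {
    stats::aggregate(list(total = events$cost[keep]),
                     by = list(patient_id = events$patient_id[keep]),
                     FUN = sum)
  } else {
    data.frame(patient_id = character(0), total = numeric(0))
  }
  out <- tibble::tibble(patient_id = patients$patient_id)
  out <- dplyr::left_join(out, tot, by = "patient_id")
  out$total[is.na(out$total)] <- 0
  out$excluded <- dead_before
  out$total[dead_before] <- NA_real_
  attr(out, "excluded") <- patients$patient_id[dead_before]
  out
}

#' Group mean with a t-based 95% confidence interval
#'
#' @param totals numeric vector of per-patient totals.
#' @param level confidence level.
#' @return list (n, mean, ci_lower, ci_upper, method = "t").
#' @export
summarize_window <- function(totals, level = 0.95) {
  totals <- totals[!is.na(totals)]
  n <- length(totals)
  m <- mean(totals)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(totals) / sqrt(n)
  list(n = n, mean = m, ci_lower = m - half, ci_upper = m + half,
       method = "t")
}

#' Paired comparison of matched test and control totals
#'
#' Two-tailed paired test on control-minus-test differences: paired t test for
#' symmetric differences, Wilcoxon signed-rank for skewed ones, with the
#' symmetric/skewed dispatch operationalised as a Shapiro-Wilk test on the
#' differences at `alpha`. Degenerate inputs (all differences equal) short-cut:
#' p = 1 when all zero, p = 0 for an exact constant shift.
#'
#' @param test,control equal-length paired vectors (the control side is the
#'   averaged effective control).
#' @param skewed force the skewed (signed-rank) path; `NULL` = decide by
#'   Shapiro-Wilk.
#' @param alpha normality threshold for the dispatch.
#' @return list (p_value, method, mean_difference, shapiro_p).
#' @export
paired_compare <- function(test, control, skewed = NULL, alpha = 0.05) {
  if (length(test) != length(control)) {
    abort_telebaci("paired vectors differ in length", "telebaci_baseline_error")
  }
  ok <- !is.na(test) & !is.na(control)
  test <- test[ok]; control <- control[ok]
  if (length(test) < 3) {
    abort_telebaci("need >= 3 pairs", "telebaci_baseline_error")
  }
  d <- control - test
  if (stats::sd(d) == 0) {
    return(list(p_value = if (all(d == 0)) 1 else 0,
                method = "degenerate (constant differences)",
                mean_difference = mean(d), shapiro_p = NA_real_))
  }
  shapiro_p <- stats::shapiro.test(d)$p.value
  if (is.null(skewed)) skewed <- shapiro_p < alpha
  if (skewed) {
    p <- stats::wilcox.test(control, test, paired = TRUE,
                            exact = FALSE)$p.value
    method <- "Wilcoxon signed-rank"
  } else {
    p <- stats::t.test(control, test, paired = TRUE)$p.value
    method <- "paired t"
  }
  list(p_value = p, method = method, mean_difference = mean(d),
       shapiro_p = shapiro_p)
}

#' Between-arm comparison of a baseline variable
#'
#' Dispatches on variable type the way baseline tables are typically built:
#' categorical variables by chi-square, switching to Fisher's exact test when
#' any expected cell count is below 5; continuous variables by the 2-sample t
#' test, switching to the Wilcoxon rank-sum test when either arm's values are
#' skewed (Shapiro-Wilk at `alpha`).
#'
#' @param x the variable (numeric, or character/factor for categorical).
#' @param arm parallel vector of group labels (exactly two groups).
#' @param alpha normality threshold for the continuous dispatch.
#' @return list (p_value, method).
#' @export
group_compare <- function(x, arm, alpha = 0.05) {
  arm <- as.factor(arm)
  if (nlevels(droplevels(arm)) != 2) {
    abort_telebaci("need exactly two non-empty groups",
                   "telebaci_baseline_error")
  }
  if (is.numeric(x)) {
    g <- split(x, arm)
    sw <- vapply(g, function(v) {
      if (stats::sd(v) == 0) 0 else stats::shapiro.test(v)$p.value
    }, numeric(1))
    if (any(sw < alpha)) {
      list(p_value = stats::wilcox.test(g[[1]], g[[2]],
                                        exact = FALSE)$p.value,
           method = "Wilcoxon rank-sum")
    } else {
      list(p_value = stats::t.test(g[[1]], g[[2]])$p.value,
           method = "2-sample t")
    }
  } else {
    tab <- table(x, arm)
    if (nrow(tab) < 2 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      abort_telebaci("degenerate contingency table (a margin is zero)",
                     "telebaci_baseline_error")
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      list(p_value = stats::fisher.test(tab)$p.value, method = "Fisher exact")
    } else {
      list(p_value = stats::chisq.test(tab)$p.value, method = "chi-square")
    }
  }
}

#' Annualised between-arm expenditure difference
#'
#' Converts the difference of two 100-day group means to AUD per year:
#' `(control - test) * 365 / window_days`.
#'
#' @param summary_control,summary_test group mean totals over the same 100-day
#'   window, AUD.
#' @param window_days window length (100).
#' @return AUD per year, full precision (round at presentation).
#' @export
annualized_group_difference <- function(summary_control, summary_test,
                                        window_days = 100) {
  (summary_control - summary_test) * 365 / window_days
}
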