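#' Binned outcome series
#'
#' A cross-patient mean outcome per signed bin relative to intervention
#' (day 0 = first monitored day; bin `b` covers days `[b*width, (b+1)*width)`,
#' half-open, so bins with `b < 0` form the before-period and `b >= 0` the
#' after-period).
#'
#' @param df tibble with columns `bin` (signed integer), `value`, `n_observed`.
#' @param bin_width bin width in days (30 for costs, 100 for hospital data).
#' @param transform scale the values are on: "identity", "sqrt" or "log".
#' @param outcome label, e.g. "medical_cost", "pharma_cost", "admissions",
#'   "los".
#' @return a `binned_series` (tibble subclass with the above attributes).
#' @export
new_binned_series <- function(df, bin_width, transform = "identity",
                              outcome = "cost") {
  stopifnot(all(c("bin", "value", "n_observed") %in% names(df)))
  transform <- match.arg(transform, c("identity", "sqrt", "log"))
  df <- tibble::as_tibble(df)[, c("bin", "value", "n_observed")]
  df <- df[order(df$bin), ]
  structure(df,
            bin_width = bin_width, transform = transform, outcome = outcome,
            class = c("binned_series", class(tibble::tibble())))
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf("<binned_series> %s, width %d d, %s scale, %d bins (%d before / %d after)\n",
              attr(x, "outcome"), attr(x, "bin_width"), attr(x, "transform"),
              nrow(x), sum(x$bin < 0), sum(x$bin >= 0)))
  NextMethod()
}

bs_width <- function(x) attr(x, "bin_width")
bs_transform <- function(x) attr(x, "transform")
bs_outcome <- function(x) attr(x, "outcome")

#' Bin dated events into intervention-synchronised periods
#'
#' Totals each patient's events into half-open bins of `width` days indexed by
#' the signed bin number relative to the patient's intervention anchor
#' (`bin = floor(day / width)`). A bin is flagged unobserved when the patient
#' died before the bin's last day (the stream is truncated, so a zero there
#' would fabricate decline); observed empty bins total zero. Events outside
#' the requested bin range land in no bin and are tallied in the `discarded`
#' attribute.
#'
#' @param events tibble with `patient_id`, `day` and the value column.
#' @param patients patient table (`patient_id`, `death_day`); every patient
#'   appears in the output even with no events.
#' @param width bin width in days.
#' @param n_before,n_after number of before / after bins; the bin range is
#'   `-n_before .. n_after - 1`.
#' @param value name of the column to total, or `NULL` to count events.
#' @return tibble (patient_id, bin, total, observed) with attribute
#'   `discarded` (tibble of out-of-range events).
#' @export
bin_events <- function(events, patients, width, n_before, n_after,
                       value = "cost") {
  v <- if (is.null(value)) rep(1, nrow(events)) else events[[value]]
  bin <- as.integer(floor(events$day / width))
  in_range <- bin >= -n_before & bin < n_after
  discarded <- tibble::tibble(patient_id = events$patient_id[!in_range],
                              day = events$day[!in_range],
                              value = v[!in_range])

  grid <- tidyr::expand_grid(patient_id = patients$patient_id,
                             bin = seq.int(-n_before, n_after - 1L))
  tot <- if (any(in_range)) {
    stats::aggregate(
      list(total = v[in_range]),
      by = list(patient_id = events$patient_id[in_range], bin = bin[in_range]),
      FUN = sum)
  } else {
    data.frame(patient_id = character(0), bin = integer(0),
               total = numeric(0))
  }
  out <- dplyr::left_join(grid, tot, by = c("patient_id", "bin"))
  out$total[is.na(out$total)] <- 0

  dd <- patients$death_day[match(out$patient_id, patients$patient_id)]
  bin_last_day <- (out$bin + 1L) * width - 1L
  out$observed <- is.na(dd) | dd >= bin_last_day
  out <- tibble::as_tibble(out)
  attr(out, "discarded") <- discarded
  out
}

#' Average per-patient binned totals into one series
#'
#' The per-bin arithmetic mean over patients observed in that bin (the trial
#' averaged all patients of an arm within each time-period number before
#' regression). Bins with zero observed patients are absent from the output
#' and downstream fits skip them.
#'
#' @param binned output of [bin_events()] (possibly several patients).
#' @param bin_width,outcome carried into the resulting [new_binned_series()].
#' @return a `binned_series` on the identity scale.
#' @export
average_patients <- function(binned, bin_width, outcome = "cost") {
  obs <- binned[binned$observed, ]
  if (nrow(obs) == 0) {
    abort_telebaci("no observed bins", "telebaci_series_error")
  }
  agg <- stats::aggregate(list(value = obs$total),
                          by = list(bin = obs$bin), FUN = mean)
  n <- stats::aggregate(list(n_observed = obs$total),
                        by = list(bin = obs$bin), FUN = length)
  df <- dplyr::left_join(agg, n, by = "bin")
  new_binned_series(df, bin_width, "identity", outcome)
}

#' Re-express a binned series on another scale
#'
#' @param series a `binned_series` on the identity scale.
#' @param transform "identity", "sqrt" or "log".
#' @return a `binned_series` on the requested scale.
#' @export
transform_series <- function(series, transform) {
  transform <- match.arg(transform, c("identity", "sqrt", "log"))
  if (bs_transform(series) != "identity") {
    abort_telebaci("`series` must be on the identity scale",
                   "telebaci_series_error")
  }
  v <- series$value
  if (transform == "sqrt" && any(v < 0)) {
    abort_telebaci("negative values: sqrt transform undefined",
                   "telebaci_series_error")
  }
  if (transform == "log" && any(v <= 0)) {
    abort_telebaci("nonpositive values: log transform undefined",
                   "telebaci_series_error")
  }
  out <- series
  out$value <- switch(transform, identity = v, sqrt = sqrt(v), log = log(v))
  attr(out, "transform") <- transform
  out
}

#' Choose the normalising transform for a binned series
#'
#' The segmented model's assumption is residual normality, so each candidate
#' transform (identity, sqrt, log) is judged by a Shapiro-Wilk test on the
#' residuals of the segmented before/after regression fitted to the
#' transformed series. The first of identity, sqrt, log whose residual
#' p-value is at least `alpha` is selected; if none passes, the transform with
#' the largest p-value. log is excluded when any bin value is nonpositive
#' (and sqrt when any is negative).
#'
#' @param series a `binned_series` on the identity scale with >= 8 observed
#'   bins.
#' @param alpha normality threshold (default .05).
#' @return list with `transform` (the choice), `p_values` (named vector over
#'   the candidates) and `series` (the transformed series).
#' @export
select_transform <- function(series, alpha = 0.05) {
  if (nrow(series) < 8) {
    abort_telebaci("need >= 8 observed bins to select a transform",
                   "telebaci_series_error")
  }
  candidates <- c("identity",
                  if (all(series$value >= 0)) "sqrt",
                  if (all(series$value > 0)) "log")
  p <- vapply(candidates, function(tr) {
    s <- transform_series(series, tr)
    res <- stats::residuals(segmented_lm(s))
    if (stats::sd(res) < 1e-12 * max(1, stats::sd(s$value))) {
      return(1)  # perfect fit: no evidence against normality
    }
    stats::shapiro.test(res)$p.value
  }, numeric(1))
  choice <- candidates[p >= alpha][1]
  if (is.na(choice)) choice <- candidates[which.max(p)]
  list(transform = choice, p_values = p,
       series = transform_series(series, choice))
}

segmented_lm <- function(series) {
  df <- data.frame(value = series$value, t = series$bin,
                   after = as.numeric(series$bin >= 0))
  stats::lm(value ~ t * after, data = df)
}

#' Per-bin difference (control - test) of two series
#'
#' The trial analysed control-minus-test differences on natural units (the
#' differences were normal without a transform); both inputs must be on the
#' identity scale with the same width and outcome. Bins absent from either
#' series are absent from the difference.
#'
#' @param control,test `binned_series` on the identity scale.
#' @return a `binned_series` of differences, outcome suffixed `_diff`.
#' @export
difference_series <- function(control, test) {
  if (bs_transform(control) != "identity" || bs_transform(test) != "identity") {
    abort_telebaci("difference series are taken on the identity scale",
                   "telebaci_series_error")
  }
  if (bs_width(control) != bs_width(test) ||
      bs_outcome(control) != bs_outcome(test)) {
    abort_telebaci("series differ in bin width or outcome",
                   "telebaci_series_error")
  }
  m <- dplyr::inner_join(
    tibble::as_tibble(control), tibble::as_tibble(test),
    by = "bin", suffix = c("_c", "_t"))
  df <- tibble::tibble(bin = m$bin, value = m$value_c - m$value_t,
                       n_observed = pmin(m$n_observed_c, m$n_observed_t))
  new_binned_series(df, bs_width(control), "identity",
                    paste0(bs_outcome(control), "_diff"))
}

#' Write binned series to CSV
#'
#' One row per bin: outcome_label, arm, bin_index, n_observed, value,
#' transform.
#'
#' @param series_by_arm named list of `binned_series` (names are arms).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_binned <- function(series_by_arm, path) {
  rows <- lapply(names(series_by_arm), function(arm) {
    s <- series_by_arm[[arm]]
    tibble::tibble(outcome_label = bs_outcome(s), arm = arm,
                   bin_index = s$bin, n_observed = s$n_observed,
                   value = s$value, transform = bs_transform(s))
  })
  utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}
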