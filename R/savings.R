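#' Convert a segment fit into an annualised natural-scale rate curve
#'
#' A sqrt-scale fit `a + b*t` (t in bins) back-transforms to a quadratic
#' natural-scale bin value `(a + b*t)^2`, and multiplying by `365/bin_width`
#' gives the instantaneous annual rate of the outcome. Identity-scale fits
#' bypass the squaring (the rate is linear, clipped at zero).
#'
#' @param fit a `segment_fit` on the sqrt or identity scale.
#' @param bin_width bin width in days (defaults to the fit's).
#' @return an object of class `annual_rate_curve` with fields scale_factor
#'   (= 365/bin_width), a, b, transform, bin_width, outcome, unit.
#' @export
annualize <- function(fit, bin_width = fit$bin_width) {
  if (!fit$transform %in% c("sqrt", "identity")) {
    abort_telebaci("annualisation expects a sqrt- or identity-scale fit",
                   "telebaci_savings_error")
  }
  outcome <- fit$outcome %||% "cost"
  unit <- if (grepl("los", outcome)) "days"
          else if (grepl("admission", outcome)) "admissions"
          else "AUD"
  structure(list(
    scale_factor = 365 / bin_width,
    a = fit$intercept,
    b = fit$slope,
    transform = fit$transform,
    bin_width = bin_width,
    outcome = outcome,
    unit = unit,
    period = fit$period
  ), class = "annual_rate_curve")
}

#' @export
print.annual_rate_curve <- function(x, ...) {
  form <- if (x$transform == "sqrt") {
    sprintf("%.4g * (%.4g %+.4g * t)^2", x$scale_factor, x$a, x$b)
  } else {
    sprintf("%.4g * max(%.4g %+.4g * t, 0)", x$scale_factor, x$a, x$b)
  }
  cat(sprintf("<annual_rate_curve> %s [%s]: rate(t bins) = %s  %s/yr\n",
              x$outcome, x$period, form, x$unit))
  invisible(x)
}

#' Evaluate an annual rate curve
#'
#' @param curve an `annual_rate_curve`.
#' @param t bin index (vectorised); days from intervention = `t * bin_width`.
#' @return annual rate of the outcome at `t`, in `unit`/year.
#' @export
curve_rate <- function(curve, t) {
  lin <- curve$a + curve$b * t
  if (curve$transform == "sqrt") curve$scale_factor * lin^2
  else curve$scale_factor * pmax(lin, 0)
}

# total outcome accrued between bins lo and hi (closed-form integral of the
# natural-scale bin value); refuses to extrapolate past a sign change of the
# transform-scale line, where the squared curve would bounce back up
integrate_curve <- function(curve, lo, hi) {
  a <- curve$a; b <- curve$b
  if ((a + b * lo) * (a + b * hi) < 0) {
    abort_telebaci(
      "curve extrapolation crosses zero on the transform scale; refusing",
      "telebaci_savings_error")
  }
  if (curve$transform == "sqrt") {
    if (b == 0) return((hi - lo) * a^2)
    ((a + b * hi)^3 - (a + b * lo)^3) / (3 * b)
  } else {
    (hi - lo) * (a + b * (hi + lo) / 2)
  }
}

#' Day at which before and after rate curves intersect
#'
#' Solved on the transform scale, where both curves are lines:
#' `t* = (a2 - a1) / (b1 - b2)`. Returned in days after intervention when the
#' root falls within the first year, else `NA` (parallel distinct lines never
#' cross; identical lines cross at day 0 by convention).
#'
#' @param before,after `annual_rate_curve`s with equal scale factors.
#' @return intersection day in `[0, 365]`, or `NA`.
#' @export
find_intersection <- function(before, after) {
  if (before$scale_factor != after$scale_factor) {
    abort_telebaci("curves have different bin widths", "telebaci_savings_error")
  }
  if (before$b == after$b) {
    return(if (before$a == after$a) 0 else NA_real_)
  }
  t_star <- (after$a - before$a) / (before$b - after$b)
  day <- t_star * before$bin_width
  if (day >= 0 && day <= 365) day else NA_real_
}

#' Model-based annual savings from the area between rate curves
#'
#' The pre-intervention trajectory is projected one year past the start of
#' intervention; the area under that projected curve is the predicted total,
#' the area under the after-curve the actual total, and their difference the
#' estimated saving over the year. When the two curves intersect within the
#' year (the intervention takes some time to act), savings are accrued only
#' from the intersection day onward; both totals then cover the
#' `[start, horizon]` window.
#'
#' @param before,after `annual_rate_curve`s for the same outcome.
#' @param horizon_days end of the accrual window, days after intervention.
#' @param start_day start of accrual; default the curve intersection (day 0
#'   when none exists in the window).
#' @return an object of class `savings_estimate`: projected_annual_total,
#'   actual_annual_total, saving, saving_pct, rate_reduction_pct (at 1 year),
#'   intersection_day, unit.
#' @export
estimate_savings <- function(before, after, horizon_days = 365,
                             start_day = NULL) {
  if (before$outcome != after$outcome) {
    abort_telebaci("curves describe different outcomes",
                   "telebaci_savings_error")
  }
  intersection <- find_intersection(before, after)
  if (is.null(start_day)) {
    start_day <- if (is.na(intersection)) 0 else intersection
  }
  w <- before$bin_width
  s <- start_day / w
  h <- horizon_days / w
  projected <- integrate_curve(before, s, h)
  actual <- integrate_curve(after, s, h)
  saving <- projected - actual
  structure(list(
    projected_annual_total = projected,
    actual_annual_total = actual,
    saving = saving,
    saving_pct = if (projected != 0) 100 * saving / projected else 0,
    rate_reduction_pct = rate_reduction(before, after, at_day = horizon_days),
    intersection_day = intersection,
    start_day = start_day,
    horizon_days = horizon_days,
    outcome = before$outcome,
    unit = before$unit
  ), class = "savings_estimate")
}

#' @export
print.savings_estimate <- function(x, ...) {
  cat(sprintf("<savings_estimate> %s: projected %.1f, actual %.1f %s over days [%.0f, %.0f]\n",
              x$outcome, x$projected_annual_total, x$actual_annual_total,
              x$unit, x$start_day, x$horizon_days))
  cat(sprintf("  saving %.1f %s (%.1f%%); rate reduction at 1 y: %.1f%%",
              x$saving, x$unit, x$saving_pct, x$rate_reduction_pct))
  if (!is.na(x$intersection_day)) {
    cat(sprintf("; curves intersect %.0f days after start", x$intersection_day))
  }
  cat("\n")
  invisible(x)
}

#' Percentage reduction in the annual rate at a given day
#'
#' `100 * (1 - rate_after(T) / rate_before(T))`, evaluated by default one year
#' after the start of intervention.
#'
#' @param before,after `annual_rate_curve`s.
#' @param at_day evaluation day (default 365).
#' @return percent reduction (negative if the rate rose).
#' @export
rate_reduction <- function(before, after, at_day = 365) {
  t <- at_day / before$bin_width
  rb <- curve_rate(before, t)
  if (rb <= 0) {
    abort_telebaci("before-curve rate is zero at the evaluation day",
                   "telebaci_savings_error")
  }
  100 * (1 - curve_rate(after, t) / rb)
}

#' Return on investment of the telemonitoring service
#'
#' @param annual_saving estimated saving, AUD per year.
#' @param annual_service_cost cost of delivering the service, AUD per year
#'   (must be positive).
#' @return the ratio saving / cost.
#' @export
roi <- function(annual_saving, annual_service_cost) {
  if (!is.numeric(annual_service_cost) || annual_service_cost <= 0) {
    abort_telebaci("`annual_service_cost` must be positive",
                   "telebaci_savings_error")
  }
  annual_saving / annual_service_cost
}
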