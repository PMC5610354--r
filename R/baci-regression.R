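#' Fit one linear segment of a binned series
#'
#' Ordinary least squares of the (transform-scale) bin value on the signed bin
#' index, over the before-period (`bin < 0`), after-period (`bin >= 0`) or all
#' bins pooled. Outlying bins are excluded first (see [exclude_outliers()])
#' unless `exclude = FALSE`.
#'
#' @param series a `binned_series`.
#' @param period "before", "after" or "pooled".
#' @param exclude apply the studentized-residual outlier rule before the final
#'   fit.
#' @return an object of class `segment_fit`: intercept, slope, n, sse, r2,
#'   adj_r2, rmse (= sqrt(sse/(n-2))), residuals (named by bin),
#'   excluded_outliers (bin indices), and the leverage quantities needed for
#'   prediction intervals.
#' @export
fit_segment <- function(series, period = c("pooled", "before", "after"),
                        exclude = TRUE) {
  period <- match.arg(period)
  df <- data.frame(t = series$bin, value = series$value)
  df <- switch(period,
               before = df[df$t < 0, ],
               after = df[df$t >= 0, ],
               pooled = df)
  if (nrow(df) < 3) {
    abort_telebaci(sprintf("need >= 3 observed bins in the %s period", period),
                   "telebaci_fit_error")
  }
  if (stats::sd(df$t) == 0) {
    abort_telebaci("zero variance in bin index", "telebaci_fit_error")
  }
  excluded <- integer(0)
  if (exclude) {
    filt <- outlier_filter(df, value ~ t)
    df <- filt$df
    excluded <- filt$excluded
  }
  segment_stats(stats::lm(value ~ t, data = df), df, period, series, excluded)
}

segment_stats <- function(fit, df, period, series, excluded) {
  res <- stats::residuals(fit)
  names(res) <- df$t
  sse <- sum(res^2)
  tss <- sum((df$value - mean(df$value))^2)
  n <- nrow(df)
  r2 <- if (tss > 0) 1 - sse / tss else 0
  adj_r2 <- if (tss > 0) 1 - (1 - r2) * (n - 1) / (n - 2) else 0
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    n = n,
    sse = sse,
    r2 = r2,
    adj_r2 = adj_r2,
    rmse = sqrt(sse / (n - 2)),
    residuals = res,
    excluded_outliers = excluded,
    x_mean = mean(df$t),
    sxx = sum((df$t - mean(df$t))^2),
    period = period,
    bin_width = bs_width(series),
    transform = bs_transform(series),
    outcome = bs_outcome(series)
  ), class = "segment_fit")
}

#' @export
print.segment_fit <- function(x, ...) {
  cat(sprintf("<segment_fit> %s [%s, %s scale]: value = %.4g %+.4g * bin  (n=%d, R2=%.3f, RMSE=%.3g)\n",
              x$outcome, x$period, x$transform,
              x$intercept, x$slope, x$n, x$r2, x$rmse))
  if (length(x$excluded_outliers)) {
    cat("  excluded bins:", paste(x$excluded_outliers, collapse = ", "), "\n")
  }
  invisible(x)
}

# iterative removal of the single worst |externally studentized residual| > 3,
# capped at 10% of the starting bins and never below 3 remaining points
outlier_filter <- function(df, formula, threshold = 3, max_frac = 0.1) {
  cap <- floor(max_frac * nrow(df))
  excluded <- integer(0)
  y_scale <- max(1, max(abs(df$value)))
  repeat {
    if (length(excluded) >= cap) break
    fit <- stats::lm(formula, data = df)
    sigma <- suppressWarnings(summary(fit)$sigma)  # perfect fits warn
    if (sigma < 1e-10 * y_scale) break
    rs <- stats::rstudent(fit)
    rs[!is.finite(rs)] <- 0
    worst <- which.max(abs(rs))
    if (length(worst) == 0 || abs(rs[worst]) <= threshold) break
    if (nrow(df) - 1 < 3) {
      warning("outlier removal stopped: fewer than 3 bins would remain",
              call. = FALSE)
      break
    }
    excluded <- c(excluded, df$t[worst])
    df <- df[-worst, ]
  }
  list(df = df, excluded = excluded)
}

#' Exclude outlying bins from a series
#'
#' Iteratively removes the bin with the largest externally studentized
#' residual exceeding 3 (in absolute value) from the stated regression, at most
#' 10% of the bins, stopping (with a warning) if fewer than 3 bins would
#' remain. Removals are recorded in the `excluded` attribute.
#'
#' @param series a `binned_series`.
#' @param segmented use the segmented before/after interaction model for the
#'   residuals (default) instead of a single line.
#' @return the pruned `binned_series` with attribute `excluded` (bin indices).
#' @export
exclude_outliers <- function(series, segmented = TRUE) {
  df <- data.frame(t = series$bin, value = series$value,
                   after = as.numeric(series$bin >= 0))
  formula <- if (segmented && length(unique(df$after)) > 1) {
    value ~ t * after
  } else {
    value ~ t
  }
  filt <- outlier_filter(df, formula)
  out <- series[!series$bin %in% filt$excluded, ]
  attr(out, "excluded") <- filt$excluded
  out
}

#' ANCOVA comparison of before and after slopes
#'
#' Fits the segmented model `value = b0 + b1*t + b2*after + b3*t*after`
#' (`after = [t >= 0]`) and tests the slope-change coefficient `b3` with a
#' two-tailed t test — the interrupted-time-series ANCOVA contrast. The
#' equivalent partial F test (segmented vs common-slope model) is reported
#' alongside. A pooled single-line fit is also produced, with an approximate t
#' test of its slope against the before-only slope (the "combined vs before"
#' contrast used to show control patients had no before/after difference).
#'
#' Outliers are excluded once, from the segmented model's studentized
#' residuals, before all fits, so the reported before/after segment fits and
#' the interaction estimate stay mutually consistent
#' (`interaction_estimate = slope_after - slope_before` exactly).
#'
#' @param series a `binned_series` with >= 3 bins in each period.
#' @param exclude apply the outlier rule first.
#' @return an object of class `slope_comparison`: fit_before, fit_after,
#'   common_fit (all `segment_fit`), interaction_estimate, se_interaction,
#'   p_interaction, p_partial_f, p_common_vs_before, excluded_outliers.
#' @export
compare_slopes <- function(series, exclude = TRUE) {
  if (sum(series$bin < 0) < 3 || sum(series$bin >= 0) < 3) {
    abort_telebaci("need >= 3 observed bins in each period",
                   "telebaci_fit_error")
  }
  work <- if (exclude) exclude_outliers(series, segmented = TRUE) else series
  excluded <- attr(work, "excluded") %||% integer(0)

  df <- data.frame(value = work$value, t = work$bin,
                   after = as.numeric(work$bin >= 0))
  full <- stats::lm(value ~ t * after, data = df)
  reduced <- stats::lm(value ~ t + after, data = df)
  cf <- suppressWarnings(summary(full)$coefficients)  # perfect fits warn
  if (nrow(cf) < 4 || any(!is.finite(cf[, 2]))) {
    abort_telebaci("degenerate design matrix in slope comparison",
                   "telebaci_fit_error")
  }
  p_partial_f <- stats::anova(reduced, full)[2, "Pr(>F)"]

  fit_before <- fit_segment(work, "before", exclude = FALSE)
  fit_after <- fit_segment(work, "after", exclude = FALSE)
  common_fit <- fit_segment(work, "pooled", exclude = FALSE)

  # Fig-2D-style contrast: combined single line vs the before-only line;
  # approximate t on the slope difference with combined standard errors
  se_pooled <- common_fit$rmse / sqrt(common_fit$sxx)
  se_before <- fit_before$rmse / sqrt(fit_before$sxx)
  t_cb <- (common_fit$slope - fit_before$slope) /
    sqrt(se_pooled^2 + se_before^2)
  df_cb <- min(common_fit$n, fit_before$n) - 2
  p_common_vs_before <- 2 * stats::pt(-abs(t_cb), df = df_cb)

  structure(list(
    fit_before = fit_before,
    fit_after = fit_after,
    common_fit = common_fit,
    interaction_estimate = unname(cf["t:after", "Estimate"]),
    se_interaction = unname(cf["t:after", "Std. Error"]),
    p_interaction = unname(cf["t:after", "Pr(>|t|)"]),
    p_partial_f = p_partial_f,
    p_common_vs_before = unname(p_common_vs_before),
    excluded_outliers = excluded,
    outcome = bs_outcome(series),
    transform = bs_transform(series),
    bin_width = bs_width(series)
  ), class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("<slope_comparison> %s (%s scale, %d-day bins)\n",
              x$outcome, x$transform, x$bin_width))
  cat(sprintf("  slope before %.4g, after %.4g; change %.4g (p = %.3g)\n",
              x$fit_before$slope, x$fit_after$slope,
              x$interaction_estimate, x$p_interaction))
  cat(sprintf("  combined-vs-before slope p = %.3g\n", x$p_common_vs_before))
  invisible(x)
}

#' 95% prediction interval of a segment fit
#'
#' Interval expected to contain a single future observation of the series at
#' bin `t`, from the standard OLS new-observation formula; symmetric about the
#' fitted value and widening with distance from the data centroid.
#'
#' @param fit a `segment_fit` with n >= 3.
#' @param t bin index (vectorised).
#' @param level coverage probability in (0, 1).
#' @return tibble with t, fit, lower, upper.
#' @export
prediction_interval <- function(fit, t, level = 0.95) {
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    abort_telebaci("`level` must be in (0, 1)", "telebaci_fit_error")
  }
  yhat <- fit$intercept + fit$slope * t
  tcrit <- stats::qt(1 - (1 - level) / 2, df = fit$n - 2)
  half <- tcrit * fit$rmse * sqrt(1 + 1 / fit$n + (t - fit$x_mean)^2 / fit$sxx)
  tibble::tibble(t = t, fit = yhat, lower = yhat - half, upper = yhat + half)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
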