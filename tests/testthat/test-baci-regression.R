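test_that("a perfect line is fitted exactly", {
  s <- new_binned_series(
    tibble::tibble(bin = 0:2, value = c(1, 2, 3), n_observed = 1L), 30)
  fit <- fit_segment(s, "after")
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r2, 1)
  expect_equal(fit$sse, 0, tolerance = 1e-20)
})

test_that("a constant series has slope 0 and r2 0", {
  s <- new_binned_series(
    tibble::tibble(bin = -5:4, value = 7, n_observed = 1L), 30)
  fit <- fit_segment(s, "pooled")
  expect_equal(fit$slope, 0)
  expect_equal(fit$r2, 0)
  expect_equal(fit$rmse, sqrt(fit$sse / (fit$n - 2)))
})

test_that("OLS coefficients match the normal-equations oracle to 1e-10", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(4:48, 1)
    s <- new_binned_series(
      tibble::tibble(bin = sort(sample(-36:11, n)),
                     value = rnorm(n, 50, 10), n_observed = 1L), 30)
    fit <- fit_segment(s, "pooled", exclude = FALSE)
    oracle <- ols_oracle(s$bin, s$value)
    expect_equal(fit$intercept, oracle[1], tolerance = 1e-10)
    expect_equal(fit$slope, oracle[2], tolerance = 1e-10)
    expect_true(fit$adj_r2 <= fit$r2)
  }
  expect_error(fit_segment(new_binned_series(
    tibble::tibble(bin = 0:1, value = 1:2, n_observed = 1L), 30), "after"),
    class = "telebaci_fit_error")
})

test_that("a noiseless halved after-slope gives the exact interaction estimate", {
  b <- 0.3
  s <- line_series(20, b, after_slope = b / 2)
  cmp <- compare_slopes(s)
  expect_equal(cmp$interaction_estimate, -b / 2, tolerance = 1e-9)
  expect_equal(cmp$interaction_estimate,
               cmp$fit_after$slope - cmp$fit_before$slope, tolerance = 1e-9)
  expect_lt(cmp$p_interaction, 1e-6)
})

test_that("interaction t-test equals the partial F-test within 1e-10", {
  set.seed(23)
  for (rep in 1:10) {
    s <- line_series(15, 0.2, noise_sd = 1.5, after_slope = 0.1)
    cmp <- compare_slopes(s, exclude = FALSE)
    expect_equal(cmp$p_interaction, cmp$p_partial_f, tolerance = 1e-10)
    expect_true(cmp$p_interaction >= 0 && cmp$p_interaction <= 1)
    expect_true(cmp$p_common_vs_before >= 0 && cmp$p_common_vs_before <= 1)
  }
})

test_that("difference-series interaction is the difference of arm interactions (noiseless)", {
  ctrl <- line_series(22, 0.25, after_slope = 0.25)      # unchanged control
  tst <- line_series(20, 0.25, after_slope = 0.10)       # reduced test slope
  d <- difference_series(ctrl, tst)
  cmp_d <- compare_slopes(d)
  cmp_c <- compare_slopes(ctrl)
  cmp_t <- compare_slopes(tst)
  expect_equal(cmp_d$interaction_estimate,
               cmp_c$interaction_estimate - cmp_t$interaction_estimate,
               tolerance = 1e-9)
})

test_that("prediction intervals are symmetric, leverage-monotone and degenerate at zero residuals", {
  s <- line_series(10, 0.5)
  fit <- fit_segment(s, "pooled")
  pi0 <- prediction_interval(fit, c(-10, 0, 20))
  expect_equal(pi0$upper - pi0$lower, rep(0, 3), tolerance = 1e-12)

  sn <- line_series(10, 0.5, noise_sd = 1, seed = 2)
  fitn <- fit_segment(sn, "pooled", exclude = FALSE)
  centre <- prediction_interval(fitn, fitn$x_mean)
  far <- prediction_interval(fitn, fitn$x_mean + 40)
  expect_gt(far$upper - far$lower, centre$upper - centre$lower)
  expect_equal(centre$fit - centre$lower, centre$upper - centre$fit)
  expect_error(prediction_interval(fitn, 0, level = 1.2),
               class = "telebaci_fit_error")
})

test_that("outlier exclusion removes exactly a planted gross outlier and nothing else", {
  clean <- line_series(10, 0.3, noise_sd = 0.5, seed = 41)
  kept <- exclude_outliers(clean)
  expect_length(attr(kept, "excluded"), 0)

  planted <- clean
  sigma <- 0.5
  victim <- which(planted$bin == -20)
  planted$value[victim] <- planted$value[victim] + 10 * sigma
  pruned <- exclude_outliers(planted)
  expect_equal(attr(pruned, "excluded"), -20)
  fit <- fit_segment(planted, "before")
  expect_equal(fit$excluded_outliers, -20)

  flat <- new_binned_series(
    tibble::tibble(bin = -5:4, value = 3, n_observed = 1L), 30)
  expect_length(attr(exclude_outliers(flat), "excluded"), 0)
})

test_that("outlier removal is capped and never empties the fit", {
  s <- line_series(10, 0.3, n_before = 6, n_after = 4, noise_sd = 0.3,
                   seed = 6)
  s$value <- s$value + c(rep(0, 4), 50, 0, 50, 0, 50, 0)  # several gross spikes
  pruned <- exclude_outliers(s, segmented = FALSE)
  expect_lte(length(attr(pruned, "excluded")), floor(0.1 * nrow(s)))
  expect_gte(nrow(pruned), 3)
})
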