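# shared fixtures built in code

# a binned series lying exactly on `a + b*t` for t in -n_before .. n_after-1
line_series <- function(a, b, n_before = 36, n_after = 12, width = 30,
                        noise_sd = 0, outcome = "cost", seed = NULL,
                        after_slope = b) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq.int(-n_before, n_after - 1L)
  mu <- ifelse(t < 0, a + b * t, a + b * 0 + after_slope * t)
  v <- mu + if (noise_sd > 0) rnorm(length(t), 0, noise_sd) else 0
  new_binned_series(
    tibble::tibble(bin = t, value = v, n_observed = 1L),
    bin_width = width, transform = "identity", outcome = outcome)
}

# small deterministic patient tables for matching tests
patient_row <- function(id, age, gender = "M", dx = "cardiovascular",
                        seifa = 3, arm = "control") {
  tibble::tibble(patient_id = id, arm = arm, age_at_intervention = age,
                 gender = gender, diagnosis_group = dx, seifa = seifa)
}

small_config <- function(...) {
  cohort_config(n_test = 8, controls_per_test = 2, seed = 11, ...)
}

# independent normal-equations OLS oracle
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}
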