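one_patient <- tibble::tibble(patient_id = "P1", death_day = NA_integer_)

test_that("bin boundaries are half-open and intervention-synchronised", {
  ev <- tibble::tibble(patient_id = "P1", day = c(-1L, 0L, 29L, 30L, -30L),
                       cost = c(1, 10, 100, 1000, 10000))
  b <- bin_events(ev, one_patient, 30, 36, 12)
  get <- function(bin) b$total[b$bin == bin]
  expect_equal(get(-1), 1 + 10000)   # day -1 and day -30 both in [-30, 0)
  expect_equal(get(0), 10 + 100)     # day 0 opens the after-period
  expect_equal(get(1), 1000)         # day 30 opens bin 1
})

test_that("uniform 1 AUD/day fills every before-bin with 30", {
  ev <- tibble::tibble(patient_id = "P1", day = -1080:-1, cost = 1)
  b <- bin_events(ev, one_patient, 30, 36, 12)
  expect_equal(b$total[b$bin < 0], rep(30, 36))
  expect_equal(b$total[b$bin >= 0], rep(0, 12))
  expect_equal(nrow(b), 48)  # 36 + 12 bins at width 30
})

test_that("width-100 binning yields bins -11..3", {
  ev <- tibble::tibble(patient_id = "P1", day = c(-1100L, 399L), cost = 1)
  b <- bin_events(ev, one_patient, 100, 11, 4)
  expect_equal(b$bin, -11:3)
  expect_equal(nrow(b), 15)
})

test_that("event mass is conserved: bins plus discards equal the raw total", {
  set.seed(8)
  ev <- tibble::tibble(patient_id = "P1",
                       day = sample(-1500:600, 400, replace = TRUE),
                       cost = rexp(400, 0.1))
  b <- bin_events(ev, one_patient, 30, 36, 12)
  disc <- attr(b, "discarded")
  expect_equal(sum(b$total) + sum(disc$value), sum(ev$cost), tolerance = 1e-10)
  # no event lands in two bins: per-bin recount oracle
  for (bin in sample(-36:11, 5)) {
    inside <- ev$day >= bin * 30 & ev$day < (bin + 1) * 30
    expect_equal(b$total[b$bin == bin], sum(ev$cost[inside]))
  }
})

test_that("death truncates bins to unobserved rather than zero", {
  pat <- tibble::tibble(patient_id = "P1", death_day = 45L)
  ev <- tibble::tibble(patient_id = "P1", day = c(-10L, 40L), cost = c(5, 7))
  b <- bin_events(ev, pat, 30, 2, 4)
  expect_true(b$observed[b$bin == -1])
  expect_true(b$observed[b$bin == 0])     # died day 45 >= bin 0's last day 29
  expect_false(b$observed[b$bin == 1])    # truncated mid-bin
  expect_false(all(b$observed[b$bin >= 2]))
  expect_equal(b$total[b$bin == 1], 7)    # the total still carries its events
})

test_that("cross-patient averaging matches the elementwise oracle", {
  pats <- tibble::tibble(patient_id = c("A", "B"),
                         death_day = NA_integer_)
  ev <- tibble::tibble(patient_id = c("A", "B"), day = c(-5L, -7L),
                       cost = c(10, 20))
  s <- average_patients(bin_events(ev, pats, 30, 2, 2), 30)
  expect_equal(s$value[s$bin == -1], 15)
  expect_equal(s$n_observed, rep(2L, 4))

  one <- average_patients(bin_events(ev[1, ], pats[1, ], 30, 2, 2), 30)
  expect_equal(one$value[one$bin == -1], 10)

  set.seed(12)
  ev2 <- tibble::tibble(
    patient_id = sample(c("A", "B"), 200, replace = TRUE),
    day = sample(-60:59, 200, replace = TRUE),
    cost = runif(200, 0, 50))
  b2 <- bin_events(ev2, pats, 30, 2, 2)
  s2 <- average_patients(b2, 30)
  oracle <- tapply(b2$total, b2$bin, mean)
  expect_equal(s2$value, as.numeric(oracle[as.character(s2$bin)]))
})

test_that("bins observed by nobody are absent and fits skip them", {
  pats <- tibble::tibble(patient_id = c("A", "B"), death_day = c(50L, 50L))
  ev <- tibble::tibble(patient_id = "A", day = -30L, cost = 3)
  s <- average_patients(bin_events(ev, pats, 30, 3, 3), 30)
  expect_true(all(s$bin <= 1))
  expect_false(2 %in% s$bin)
})

test_that("transform selection recovers the generating transform", {
  # exactly linear series: identity retained
  lin <- line_series(10, 0.2)
  sel <- select_transform(lin)
  expect_equal(sel$transform, "identity")

  # square of a noisy line: sqrt is the generating transform and is selected
  set.seed(1)
  t <- -36:11
  sq <- new_binned_series(
    tibble::tibble(bin = t, value = (2 + 0.5 * (t + 36) + rnorm(48, 0, 0.05))^2,
                   n_observed = 1L), 30)
  sel2 <- select_transform(sq)
  expect_equal(sel2$transform, "sqrt")
  expect_lt(sel2$p_values["identity"], 0.05)
  expect_gte(sel2$p_values["sqrt"], 0.05)

  # a zero bin removes log from the candidate set
  z <- lin
  z$value[1] <- 0
  selz <- select_transform(z)
  expect_false("log" %in% names(selz$p_values))
  expect_error(transform_series(z, "log"), class = "telebaci_series_error")
  expect_error(select_transform(lin[1:5, ]), class = "telebaci_series_error")
})

test_that("difference series is control minus test on natural units", {
  a <- line_series(10, 0.1)
  b <- a
  b$value <- a$value + 5
  d <- difference_series(b, a)
  expect_equal(d$value, rep(5, nrow(a)))
  expect_equal(difference_series(a, a)$value, rep(0, nrow(a)))

  set.seed(3)
  r1 <- line_series(10, 0.1, noise_sd = 2)
  r2 <- line_series(12, 0.15, noise_sd = 2)
  expect_equal(difference_series(r1, r2)$value, r1$value - r2$value)

  expect_error(difference_series(transform_series(a, "sqrt"), a),
               class = "telebaci_series_error")
})
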