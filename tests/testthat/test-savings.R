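make_fit <- function(a, b, transform = "sqrt", width = 30, outcome = "cost",
                     period = "before") {
  structure(list(intercept = a, slope = b, transform = transform,
                 bin_width = width, outcome = outcome, period = period),
            class = "segment_fit")
}

test_that("annualisation back-transforms to the closed-form quadratic rate", {
  flat <- annualize(make_fit(10, 0))
  expect_equal(curve_rate(flat, 0), 100 * 365 / 30)
  expect_equal(curve_rate(flat, 7), 100 * 365 / 30)

  zero <- annualize(make_fit(0, 0))
  expect_equal(curve_rate(zero, 5), 0)

  set.seed(14)
  for (rep in 1:5) {
    a <- runif(1, 5, 20); b <- runif(1, -0.3, 0.3)
    cv <- annualize(make_fit(a, b))
    t <- seq(-5, 12, length.out = 100)
    expect_equal(curve_rate(cv, t), (a + b * t)^2 * 365 / 30,
                 tolerance = 1e-12)
  }

  lin <- annualize(make_fit(3, -1, transform = "identity", width = 100,
                            outcome = "los"))
  expect_equal(curve_rate(lin, 1), 2 * 365 / 100)
  expect_equal(curve_rate(lin, 10), 0)  # clipped at zero
  expect_equal(lin$unit, "days")
})

test_that("curve intersections solve the sqrt-scale root", {
  w <- 30
  b1 <- annualize(make_fit(10, 1))
  expect_equal(find_intersection(b1, b1), 0)  # identical curves: convention

  a2 <- annualize(make_fit(11, 0, period = "after"))
  expect_equal(find_intersection(b1, a2), 30)  # t* = 1 bin = 30 days

  par <- annualize(make_fit(12, 1, period = "after"))
  expect_true(is.na(find_intersection(b1, par)))  # parallel, distinct

  set.seed(19)
  for (rep in 1:20) {
    a1 <- runif(1, 8, 15); s1 <- runif(1, 0.05, 0.4)
    cb <- annualize(make_fit(a1, s1))
    t_star <- runif(1, 0.5, 11)
    s2 <- s1 - runif(1, 0.05, 0.3)
    ca <- annualize(make_fit(a1 + (s1 - s2) * t_star, s2, period = "after"))
    got <- find_intersection(cb, ca)
    # bisection oracle on the squared (natural-scale) curves
    f <- function(t) curve_rate(cb, t) - curve_rate(ca, t)
    root <- uniroot(f, c(t_star - 0.45, t_star + 0.45), tol = 1e-12)$root
    expect_equal(got, root * w, tolerance = 1e-6)
  }
})

test_that("savings follow the closed-form area between curves", {
  b <- annualize(make_fit(10, 0.2))
  expect_equal(estimate_savings(b, b)$saving, 0)
  expect_equal(estimate_savings(b, b)$saving_pct, 0)
  expect_equal(estimate_savings(b, b)$rate_reduction_pct, 0)

  # constant 1000/yr vs 500/yr on the identity scale: rectangle areas
  scale <- 365 / 30
  cb <- annualize(make_fit(1000 / scale, 0, transform = "identity"))
  ca <- annualize(make_fit(500 / scale, 0, transform = "identity",
                           period = "after"))
  sv <- estimate_savings(cb, ca, start_day = 0)
  expect_equal(sv$projected_annual_total, 1000)
  expect_equal(sv$actual_annual_total, 500)
  expect_equal(sv$saving, 500)
  expect_equal(sv$saving_pct, 50)

  # after-curve above before-curve: negative saving reported as such
  swapped <- estimate_savings(ca, cb, start_day = 0)
  expect_equal(swapped$saving, -500)
})

test_that("closed-form quadratic areas agree with adaptive quadrature", {
  set.seed(29)
  for (rep in 1:25) {
    a1 <- runif(1, 6, 18); b1 <- runif(1, -0.1, 0.3)
    a2 <- runif(1, 6, 18); b2 <- runif(1, -0.1, 0.3)
    cb <- annualize(make_fit(a1, b1))
    ca <- annualize(make_fit(a2, b2, period = "after"))
    sv <- estimate_savings(cb, ca, start_day = 0)
    q_before <- integrate(function(t) (a1 + b1 * t)^2, 0, 365 / 30,
                          rel.tol = 1e-12)$value
    q_after <- integrate(function(t) (a2 + b2 * t)^2, 0, 365 / 30,
                         rel.tol = 1e-12)$value
    expect_equal(sv$projected_annual_total, q_before, tolerance = 1e-8)
    expect_equal(sv$actual_annual_total, q_after, tolerance = 1e-8)
    # antisymmetry under swapping the curves
    expect_equal(estimate_savings(ca, cb, start_day = 0)$saving, -sv$saving,
                 tolerance = 1e-10)
  }
})

test_that("extrapolation past a sqrt-scale sign change is refused", {
  cb <- annualize(make_fit(2, -0.5))
  ca <- annualize(make_fit(2, -0.1, period = "after"))
  expect_error(estimate_savings(cb, ca, start_day = 0),
               class = "telebaci_savings_error")
})

test_that("rate reduction at one year matches the pointwise ratio", {
  cb <- annualize(make_fit(10, 0.2))
  expect_equal(rate_reduction(cb, cb), 0)

  # after-rate exactly half the before-rate at day 365
  t1 <- 365 / 30
  target <- (10 + 0.2 * t1) / sqrt(2)
  ca <- annualize(make_fit(target, 0, period = "after"))
  expect_equal(rate_reduction(cb, ca), 50, tolerance = 1e-10)

  zero <- annualize(make_fit(0, 0))
  expect_error(rate_reduction(zero, cb), class = "telebaci_savings_error")
})

test_that("return on investment is the plain savings ratio", {
  expect_equal(roi(19000, 2760), 6.884058, tolerance = 1e-6)
  expect_equal(roi(0, 100), 0)
  expect_equal(roi(100, 100), 1)
  expect_error(roi(100, 0), class = "telebaci_savings_error")
})
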