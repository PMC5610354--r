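#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used when
#' reproducing printed tables (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by a relative epsilon so values stored just below .5 (e.g. 5.675
  # represented as 5.67499...) still round up
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

abort_telebaci <- function(msg, class) {
  stop(structure(
    class = c(class, "telebaci_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0 | x > 1)) {
    abort_telebaci(sprintf("`%s` must be a probability in [0, 1]", name),
                   "telebaci_config_error")
  }
  invisible(x)
}

check_weights <- function(w, name) {
  if (!is.numeric(w) || any(is.na(w)) || any(w < 0)) {
    abort_telebaci(sprintf("`%s` must be nonnegative weights", name),
                   "telebaci_config_error")
  }
  if (sum(w) <= 0) {
    abort_telebaci(sprintf("`%s` has zero total weight", name),
                   "telebaci_config_error")
  }
  if (abs(sum(w) - 1) > 1e-9) {
    abort_telebaci(sprintf("`%s` must sum to 1 (within 1e-9)", name),
                   "telebaci_config_error")
  }
  invisible(w)
}
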