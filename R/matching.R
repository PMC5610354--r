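#' Case-match control candidates to test patients
#'
#' Greedy nearest-neighbour matching without replacement, mirroring the trial's
#' automatic case matching: controls must agree exactly with the test patient
#' on gender and diagnosis group (hard constraints); among eligible candidates
#' the distance is a weighted sum `w_age * |age difference| / 10 +
#' w_seifa * |SEIFA difference|`, and each test patient receives its `k_max`
#' closest available controls. Test patients are processed in ascending age
#' (ties broken by patient_id), candidate ties by lexicographic patient_id, so
#' the assignment is deterministic.
#'
#' Test patients with no eligible candidate are *reported* in the
#' `unmatched` attribute (with a warning), never silently dropped.
#'
#' @param tests tibble of test patients (patient_id, age_at_intervention,
#'   gender, diagnosis_group, seifa).
#' @param pool tibble of control candidates, disjoint from `tests`.
#' @param k_max maximum controls per test patient, 1-4.
#' @param weights length-2 numeric, weights for the age and SEIFA terms.
#' @return tibble of class `matched_pairs`: test_id, control_ids (';'-joined),
#'   n_controls, match_distance (mean distance over selected controls); the
#'   `unmatched` attribute lists test patients with no eligible control.
#' @export
match_controls <- function(tests, pool, k_max = 2,
                           weights = c(age = 1, seifa = 1)) {
  if (!k_max %in% 1:4) {
    abort_telebaci("`k_max` must be in 1..4", "telebaci_match_error")
  }
  if (nrow(pool) == 0) {
    abort_telebaci(
      paste0("empty control pool; unmatched test patients: ",
             paste(tests$patient_id, collapse = ", ")),
      "telebaci_match_error")
  }
  if (any(pool$patient_id %in% tests$patient_id)) {
    abort_telebaci("`pool` must be disjoint from `tests`",
                   "telebaci_match_error")
  }

  ord <- order(tests$age_at_intervention, tests$patient_id)
  tests <- tests[ord, ]
  available <- rep(TRUE, nrow(pool))

  rows <- vector("list", nrow(tests))
  unmatched <- character(0)
  for (i in seq_len(nrow(tests))) {
    tp <- tests[i, ]
    elig <- available &
      pool$gender == tp$gender &
      pool$diagnosis_group == tp$diagnosis_group
    if (!any(elig)) {
      unmatched <- c(unmatched, tp$patient_id)
      rows[[i]] <- tibble::tibble(test_id = tp$patient_id,
                                  control_ids = NA_character_,
                                  n_controls = 0L,
                                  match_distance = NA_real_)
      next
    }
    d <- weights[[1]] * abs(pool$age_at_intervention - tp$age_at_intervention) / 10 +
      weights[[2]] * abs(pool$seifa - tp$seifa)
    cand <- which(elig)
    cand <- cand[order(d[cand], pool$patient_id[cand])]
    take <- cand[seq_len(min(k_max, length(cand)))]
    available[take] <- FALSE
    rows[[i]] <- tibble::tibble(
      test_id = tp$patient_id,
      control_ids = paste(pool$patient_id[take], collapse = ";"),
      n_controls = length(take),
      match_distance = mean(d[take])
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$test_id), ]
  if (length(unmatched) > 0) {
    warning(sprintf("%d test patient(s) had no eligible control: %s",
                    length(unmatched), paste(unmatched, collapse = ", ")),
            call. = FALSE)
  }
  attr(out, "unmatched") <- unmatched
  class(out) <- c("matched_pairs", class(out))
  out
}

#' Average the binned series of multiple matched controls
#'
#' When a test patient has more than one control, the controls' data are
#' averaged into a single effective matched partner: the per-bin arithmetic
#' mean over the controls observed in that bin. Bins where some controls are
#' unobserved (after death) use the mean of the remaining ones; a bin with no
#' observed control is flagged unobserved.
#'
#' @param series_list list of per-control binned-total tibbles
#'   (bin, total, observed), all sharing the same bin structure.
#' @return one binned-total tibble (bin, total, observed) for the effective
#'   control.
#' @export
average_controls <- function(series_list) {
  if (length(series_list) == 0) {
    abort_telebaci("no control series supplied", "telebaci_match_error")
  }
  bins <- series_list[[1]]$bin
  for (s in series_list) {
    if (!identical(s$bin, bins)) {
      abort_telebaci("control series do not share a bin structure",
                     "telebaci_match_error")
    }
  }
  obs <- vapply(series_list, function(s) s$observed, logical(length(bins)))
  val <- vapply(series_list, function(s) s$total, numeric(length(bins)))
  obs <- matrix(obs, nrow = length(bins))
  val <- matrix(val, nrow = length(bins))
  n_obs <- rowSums(obs)
  if (all(n_obs == 0)) {
    abort_telebaci("no bin is observed for any control",
                   "telebaci_match_error")
  }
  total <- ifelse(n_obs > 0, rowSums(val * obs) / pmax(n_obs, 1), NA_real_)
  tibble::tibble(bin = bins, total = total, observed = n_obs > 0)
}

#' Write matched pairs to CSV
#'
#' @param pairs a `matched_pairs` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.csv(as.data.frame(pairs), path, row.names = FALSE)
  invisible(path)
}
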