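# Occlusion-pressure prediction equations and threshold screening.
#
# Pmus_predicted    = k1 * mean(delta_Pocc)                     (k1 < 0)
# dPL_dyn_predicted = delta_Paw_dyn - k2 * mean(delta_Pocc)     (k2 > 0)
#
# Because delta_Pocc is negative when the patient makes inspiratory effort,
# both predictions are nonnegative and increase as the occlusion deflection
# deepens. Prediction is only defined for delta_Pocc < 0: without effort
# the esophageal swing is positive and uncorrelated with the occlusion.

#' Conversion factors between quasi-static and dynamic swings
#'
#' Defaults are the rounded values used for external validation:
#' `k1 = -3/4` (dynamic Pmus per unit occlusion pressure) and `k2 = 2/3`
#' (dynamic esophageal swing per unit occlusion pressure). Cohort-specific
#' factors derived with [derive_conversion_factors()] may override them.
#'
#' @param k1 Negative dimensionless factor, Pmus per unit delta-Pocc.
#' @param k2 Positive dimensionless factor in (0, 1.3], delta-Pes per unit
#'   delta-Pocc.
#' @param k1_ci,k2_ci Optional 95% CIs (length-2 numeric).
#' @param n_recordings,n_patients,method Provenance fields filled by
#'   [derive_conversion_factors()].
#' @return An object of class `pocc_factors`.
#' @export
conversion_factors <- function(k1 = -3 / 4, k2 = 2 / 3,
                               k1_ci = NULL, k2_ci = NULL,
                               n_recordings = NA_integer_,
                               n_patients = NA_integer_,
                               method = "fixed") {
  check_number(k1, "k1", upper = 0, allow_equal_upper = FALSE)
  check_number(k2, "k2", 0, 1.3, allow_equal_lower = FALSE)
  structure(
    list(k1 = k1, k2 = k2, k1_ci = k1_ci, k2_ci = k2_ci,
         n_recordings = n_recordings, n_patients = n_patients,
         method = method),
    class = "pocc_factors"
  )
}

#' @export
print.pocc_factors <- function(x, ...) {
  fmt_ci <- function(ci) {
    if (is.null(ci)) "" else sprintf(" (95%% CI %.3f, %.3f)", ci[1], ci[2])
  }
  cat(sprintf("<pocc_factors> k1 = %.3f%s, k2 = %.3f%s [%s]\n",
              x$k1, fmt_ci(x$k1_ci), x$k2, fmt_ci(x$k2_ci), x$method))
  invisible(x)
}

#' Randomly select occlusion measurements for prediction
#'
#' Mimics bedside use of a small number of occlusion maneuvers: a seeded
#' uniform sample without replacement of `n` occlusion pressures.
#'
#' @param pocc_values Numeric vector of occlusion pressures (cm H2O).
#' @param n Number of occlusions to use (default 3).
#' @param seed Optional integer seed for reproducible selection.
#' @return Numeric vector of length `n`.
#' @export
select_occlusions <- function(pocc_values, n = 3, seed = NULL) {
  check_count(n, "n", 1)
  if (length(pocc_values) < n) {
    abort(sprintf(
      "only %d occlusion(s) available but %d requested; rerun with n = %d to use the full set",
      length(pocc_values), n, length(pocc_values)
    ))
  }
  if (length(pocc_values) == n) return(pocc_values)
  if (!is.null(seed)) set.seed(seed)
  pocc_values[sample.int(length(pocc_values), n)]
}

check_pocc_negative <- function(pocc_values) {
  if (length(pocc_values) == 0 || any(!is.finite(pocc_values))) {
    abort("occlusion pressures must be finite and non-empty")
  }
  if (any(pocc_values >= 0)) {
    abort(paste(
      "all occlusion pressures must be negative: a nonnegative delta-Pocc",
      "indicates absent inspiratory effort, for which the prediction",
      "equations are undefined"
    ))
  }
  invisible(pocc_values)
}

#' Predict dynamic respiratory muscle pressure from occlusion pressure
#'
#' @param pocc_values Occlusion pressures (cm H2O), all negative.
#' @param factors A [conversion_factors()] object.
#' @return Predicted mean Pmus, cm H2O (nonnegative).
#' @examples
#' predict_pmus(c(-18, -20, -22), conversion_factors())  # 15
#' @export
predict_pmus <- function(pocc_values, factors = conversion_factors()) {
  stopifnot(inherits(factors, "pocc_factors"))
  check_pocc_negative(pocc_values)
  factors$k1 * mean(pocc_values)
}

#' Predict dynamic transpulmonary driving pressure from occlusion pressure
#'
#' @param delta_paw_dyn Airway driving pressure (peak Paw - PEEP), cm H2O.
#' @param pocc_values Occlusion pressures (cm H2O), all negative.
#' @param factors A [conversion_factors()] object.
#' @return Predicted delta-PL,dyn, cm H2O.
#' @export
predict_delta_pl <- function(delta_paw_dyn, pocc_values,
                             factors = conversion_factors()) {
  stopifnot(inherits(factors, "pocc_factors"))
  check_number(delta_paw_dyn, "delta_paw_dyn", 0)
  check_pocc_negative(pocc_values)
  delta_paw_dyn - factors$k2 * mean(pocc_values)
}

#' Screen a recording for excessive effort and lung stress
#'
#' Runs occlusion selection and both prediction equations on a valid
#' recording summary and flags each screening threshold with a strict
#' inequality. Recordings that failed the esophageal-validity filter are
#' refused.
#'
#' @param summary A one-row recording summary from [summarize_recording()]
#'   (or one row of [analyze_cohort()] output).
#' @param factors A [conversion_factors()] object.
#' @param pmus_thresholds,pl_thresholds Screening thresholds, cm H2O.
#' @param n_occ Number of occlusions used for prediction.
#' @param seed Optional seed for the occlusion selection.
#' @return A one-row tibble: identifiers, `pmus_pred`, `delta_pl_pred`,
#'   `pocc_used` (list-column), and logical flags `pmus_gt10`, `pmus_gt15`,
#'   `pl_gt15`, `pl_gt20` (names follow the default thresholds).
#' @export
screen_recording <- function(summary, factors = conversion_factors(),
                             pmus_thresholds = c(10, 15),
                             pl_thresholds = c(15, 20),
                             n_occ = 3, seed = NULL) {
  if (nrow(summary) != 1) abort("`summary` must be a single recording row")
  if (!isTRUE(summary$valid)) {
    abort(paste(
      "recording failed the esophageal-validity filter",
      "(occlusion/esophageal swing ratio outside 0.7-1.3):",
      "refusing to predict from an unreliable Pes signal"
    ))
  }
  pocc <- select_occlusions(summary$pocc_values[[1]], n = n_occ, seed = seed)
  pmus_pred <- predict_pmus(pocc, factors)
  pl_pred <- predict_delta_pl(summary$mean_delta_paw, pocc, factors)
  flags <- c(
    setNames(as.list(pmus_pred > pmus_thresholds),
             sprintf("pmus_gt%g", pmus_thresholds)),
    setNames(as.list(pl_pred > pl_thresholds),
             sprintf("pl_gt%g", pl_thresholds))
  )
  out <- tibble(
    patient = summary$patient, day = summary$day,
    pmus_pred = pmus_pred, delta_pl_pred = pl_pred,
    pocc_used = list(pocc)
  )
  for (nm in names(flags)) out[[nm]] <- flags[[nm]]
  out
}

#' Screen every valid recording of a cohort
#'
#' @param summaries Tibble of recording summaries ([analyze_cohort()]).
#' @param ... Passed to [screen_recording()].
#' @param seed Optional base seed; recording `i` uses a deterministic child
#'   seed.
#' @return Tibble of screening rows for the valid recordings.
#' @export
screen_cohort <- function(summaries, ..., seed = NULL) {
  rows <- list()
  for (i in seq_len(nrow(summaries))) {
    row <- summaries[i, ]
    if (!isTRUE(row$valid)) next
    s <- if (is.null(seed)) NULL else child_seed(seed, i)
    rows[[length(rows) + 1]] <- screen_recording(row, ..., seed = s)
  }
  bind_rows(rows)
}
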