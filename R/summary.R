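# Recording-level summaries and the esophageal-validity filter.

#' Summarize a recording's breath metrics
#'
#' Means of the dynamic quantities are taken over non-occluded breaths
#' only; the occlusion pressure is averaged over occluded breaths. The
#' esophageal-validity ratio is the mean, within occluded breaths, of
#' `delta_pocc / delta_pes` (both negative during an occlusion, so the
#' ratio is positive; under the quasi-static identity the two swings are
#' equal and the ratio is 1). Recordings whose ratio falls outside the
#' validity band are flagged invalid and must not be used for prediction:
#' a miscalibrated esophageal balloon scales `delta_pes` and pushes the
#' ratio off 1. The band is inclusive at both ends.
#'
#' @param metrics Output of [breath_metrics()].
#' @param validity_band Two-sided inclusive band for the
#'   occlusion-to-esophageal ratio, default `c(0.7, 1.3)`.
#' @return A one-row tibble: `patient`, `day`, `n_breaths` (non-occluded),
#'   `n_occlusions`, `mean_pmus`, `mean_delta_pes`, `mean_delta_paw`,
#'   `mean_delta_pl_dyn`, `mean_ptp_mus`, `mean_delta_pocc`,
#'   `pocc_pes_ratio`, `valid`, plus a `pocc_values` list-column with the
#'   individual occlusion pressures.
#' @export
summarize_recording <- function(metrics, validity_band = c(0.7, 1.3)) {
  stopifnot(length(validity_band) == 2, validity_band[1] < validity_band[2])
  meta <- attr(metrics, "meta")
  flowing <- filter(metrics, !.data$occluded)
  occl <- filter(metrics, .data$occluded)
  if (nrow(flowing) == 0) {
    abort("recording has no non-occluded breaths to summarize")
  }

  if (nrow(occl) == 0) {
    warn("recording has no occlusions: validity ratio undefined, marked invalid")
    ratio <- NA_real_
  } else {
    per <- occl$delta_pocc / occl$delta_pes
    per[!is.finite(per) | occl$delta_pes >= 0] <- NA_real_
    ratio <- mean(per, na.rm = TRUE)
  }
  valid <- is.finite(ratio) && ratio >= validity_band[1] &&
    ratio <= validity_band[2]

  tibble(
    patient = meta$patient %||% NA_character_,
    day = meta$day %||% NA_integer_,
    n_breaths = nrow(flowing),
    n_occlusions = nrow(occl),
    mean_pmus = mean(flowing$pmus_peak),
    mean_delta_pes = mean(flowing$delta_pes),
    mean_delta_paw = mean(flowing$delta_paw_dyn),
    mean_delta_pl_dyn = mean(flowing$delta_pl_dyn),
    mean_ptp_mus = mean(flowing$ptp_mus),
    mean_delta_pocc = if (nrow(occl) > 0) mean(occl$delta_pocc) else NA_real_,
    pocc_pes_ratio = ratio,
    valid = valid,
    pocc_values = list(occl$delta_pocc)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Neural-drive invariance check on peak Edi
#'
#' A single whole-breath occlusion should not change respiratory drive:
#' peak Edi of each occluded breath is compared with the mean peak Edi of
#' the adjacent non-occluded breaths, and the differences are summarized as
#' a mean and 1.96 SD limits of agreement.
#'
#' @param metrics Output of [breath_metrics()].
#' @param min_occlusions Minimum number of occlusions required.
#' @return A one-row tibble `mean_diff`, `loa` (uV), `n_occlusions`, or
#'   `NULL` (with a message) when the Edi channel is absent.
#' @export
edi_drive_check <- function(metrics, min_occlusions = 3) {
  if (!"edi_peak" %in% names(metrics) || all(is.na(metrics$edi_peak))) {
    inform("Edi channel absent: drive-invariance check skipped")
    return(invisible(NULL))
  }
  occ_idx <- which(metrics$occluded)
  if (length(occ_idx) < min_occlusions) {
    abort(sprintf("at least %d occlusions are required (found %d)",
                  min_occlusions, length(occ_idx)))
  }
  flow_idx <- which(!metrics$occluded)
  diffs <- vapply(occ_idx, function(j) {
    before <- flow_idx[flow_idx < j]
    after <- flow_idx[flow_idx > j]
    neigh <- c(
      if (length(before) > 0) metrics$edi_peak[max(before)],
      if (length(after) > 0) metrics$edi_peak[min(after)]
    )
    metrics$edi_peak[j] - mean(neigh)
  }, numeric(1))
  tibble(
    mean_diff = mean(diffs),
    loa = 1.96 * sd(diffs),
    n_occlusions = length(occ_idx)
  )
}

#' Segment, detect occlusions, and summarize a recording in one call
#'
#' @inheritParams breath_metrics
#' @inheritParams summarize_recording
#' @param ... Passed on to [breath_metrics()].
#' @return A list with `breaths`, `metrics` and `summary`.
#' @export
analyze_recording <- function(rec, ecw = NULL, set_peep = NULL,
                              validity_band = c(0.7, 1.3), ...) {
  breaths <- segment_breaths(rec)
  breaths <- detect_occlusions(rec, breaths)
  metrics <- breath_metrics(rec, breaths, ecw = ecw, set_peep = set_peep,
                            ...)
  list(
    breaths = breaths,
    metrics = metrics,
    summary = summarize_recording(metrics, validity_band = validity_band)
  )
}

#' Analyze every recording of a simulated cohort
#'
#' @param cohort A [simulate_cohort()] object (or a named list of
#'   recordings).
#' @inheritParams summarize_recording
#' @param ... Passed on to [breath_metrics()].
#' @return A tibble with one summary row per recording (see
#'   [summarize_recording()]).
#' @export
analyze_cohort <- function(cohort, validity_band = c(0.7, 1.3), ...) {
  recs <- if (inherits(cohort, "pocc_cohort")) cohort$recordings else cohort
  rows <- lapply(recs, function(rec) {
    analyze_recording(rec, validity_band = validity_band, ...)$summary
  })
  bind_rows(rows)
}
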