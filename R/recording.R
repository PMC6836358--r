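#' Construct a multi-channel waveform recording
#'
#' A recording is a tibble with columns `time` (s, uniform grid), `flow`
#' (L/s, inspiration positive), `paw` (cm H2O), `pes` (cm H2O) and
#' optionally `edi` (uV), carrying the sampling rate and per-recording
#' metadata as attributes. All analysis functions accept it as their first
#' argument.
#'
#' @param data Data frame with columns `time`, `flow`, `paw`, `pes` and
#'   optionally `edi`.
#' @param sampling_rate Sampling rate in Hz. If `NULL`, inferred from the
#'   time column.
#' @param meta Named list of metadata. `peep` (set PEEP, cm H2O) is required
#'   by occlusion detection; `patient`, `day`, `mode`, `sex`, `height_cm`
#'   are used downstream where present.
#'
#' @return A tibble of class `pocc_recording`.
#' @export
as_recording <- function(data, sampling_rate = NULL, meta = list()) {
  data <- as_tibble(data)
  required <- c("time", "flow", "paw", "pes")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("recording is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) < 2) abort("recording must contain at least 2 samples")
  channels <- intersect(c("time", "flow", "paw", "pes", "edi"), names(data))
  for (ch in channels) {
    bad <- which(!is.finite(data[[ch]]))
    if (length(bad) > 0) {
      abort(sprintf("non-finite value in column '%s' at row %d",
                    ch, bad[1]))
    }
  }
  dt <- diff(data$time)
  if (is.null(sampling_rate)) sampling_rate <- 1 / median(dt)
  if (any(abs(dt - 1 / sampling_rate) > 1e-6)) {
    row <- which(abs(dt - 1 / sampling_rate) > 1e-6)[1]
    abort(sprintf(
      "time grid is not uniform at rate %g Hz (first offending row: %d)",
      sampling_rate, row + 1
    ))
  }
  structure(
    data,
    class = c("pocc_recording", class(as_tibble(data))),
    sampling_rate = sampling_rate,
    meta = meta
  )
}

#' @export
print.pocc_recording <- function(x, ...) {
  meta <- rec_meta(x)
  cat(sprintf(
    "<pocc_recording> %d samples at %g Hz (%.1f s)%s\n",
    nrow(x), rec_rate(x), nrow(x) / rec_rate(x),
    if (!is.null(meta$patient)) {
      sprintf(" - patient %s day %s", meta$patient, meta$day)
    } else ""
  ))
  NextMethod()
}

#' Sampling rate of a recording
#' @param rec A [as_recording()] object (or any data frame with a uniform
#'   `time` column).
#' @return Sampling rate in Hz.
#' @export
rec_rate <- function(rec) {
  sr <- attr(rec, "sampling_rate")
  if (is.null(sr)) sr <- 1 / median(diff(rec$time))
  sr
}

#' Metadata of a recording
#' @inheritParams rec_rate
#' @return Named list (possibly empty).
#' @export
rec_meta <- function(rec) {
  meta <- attr(rec, "meta")
  if (is.null(meta)) list() else meta
}

#' Per-breath ground truth attached to a simulated recording
#'
#' @inheritParams rec_rate
#' @return A tibble with one row per simulated breath (onset index,
#'   quasi-static amplitude, occlusion flag, true per-breath effort
#'   quantities), or `NULL` for recordings that were not simulated.
#' @export
rec_truth <- function(rec) {
  attr(rec, "truth")
}
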