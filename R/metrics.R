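# Per-breath reference quantities: tidal volume, esophageal swing,
# chest-wall recoil, muscle pressure and its pressure-time product,
# dynamic transpulmonary driving pressure, and occlusion pressure.

#' Transpulmonary pressure by samplewise subtraction
#'
#' `PL(t) = Paw(t) - Pes(t)`. Adding the same constant to both channels
#' leaves PL unchanged.
#'
#' @param paw Airway pressure samples (cm H2O), or a data frame with `paw`
#'   and `pes` columns.
#' @param pes Esophageal pressure samples (cm H2O); ignored when `paw` is a
#'   data frame.
#' @return Numeric vector of PL samples.
#' @export
transpulmonary <- function(paw, pes = NULL) {
  if (is.data.frame(paw)) {
    pes <- paw$pes
    paw <- paw$paw
  }
  if (length(paw) != length(pes)) {
    abort("paw and pes must have the same length")
  }
  paw - pes
}

#' Predicted chest-wall elastance from demographics
#'
#' Deterministic estimate used when no direct chest-wall elastance
#' measurement is available: a calibration constant divided by the
#' predicted vital capacity (simplified adult spirometric reference,
#' male `0.0576 h - 4.34` L, female `0.0443 h - 2.89` L at height `h` cm).
#' The constant is calibrated so that a 175 cm male yields 5 cm H2O/L;
#' elastance decreases monotonically with predicted vital capacity. The
#' estimator is a configurable placeholder: pass `ecw_override` to use a
#' measured or alternative value unchanged.
#'
#' @param sex `"male"` or `"female"`.
#' @param height_cm Height in cm.
#' @param ecw_override Optional explicit elastance (cm H2O/L), returned
#'   unchanged with a provenance message.
#' @return Chest-wall elastance, cm H2O/L.
#' @export
predicted_chest_wall_elastance <- function(sex = NULL, height_cm = NULL,
                                           ecw_override = NULL) {
  if (!is.null(ecw_override)) {
    check_number(ecw_override, "ecw_override", 0, allow_equal_lower = FALSE)
    inform(sprintf("using explicit chest-wall elastance %.3g cm H2O/L",
                   ecw_override))
    return(ecw_override)
  }
  if (is.null(sex) || is.null(height_cm) || is.na(height_cm)) {
    abort(paste(
      "demographics (sex, height_cm) are required to predict chest-wall",
      "elastance; supply `ecw_override` to use an explicit value"
    ))
  }
  sex <- match.arg(sex, c("male", "female"))
  check_number(height_cm, "height_cm", 100, 230)
  vc <- if (sex == "male") 0.0576 * height_cm - 4.34 else
    0.0443 * height_cm - 2.89
  if (vc <= 0) abort("predicted vital capacity is non-positive")
  cal <- 5 * (0.0576 * 175 - 4.34)
  cal / vc
}

#' Per-breath physiologic metrics
#'
#' For each non-occluded breath: tidal volume as the drift-corrected
#' time-integral of flow over inspiration (a constant flow offset is
#' removed so that volume returns to baseline at breath end); the
#' esophageal swing `delta_pes = min(Pes - Pes_onset)` over inspiration;
#' running chest-wall recoil `Pcw(t) = ecw * V(t)`; muscle pressure
#' `Pmus(t) = Pcw(t) - (Pes(t) - Pes_onset)` (zero at onset by
#' construction), its inspiratory peak, and its pressure-time product
#' (integral of `Pmus` clipped at zero); the dynamic transpulmonary driving
#' pressure as the inspiratory rise of `PL = Paw - Pes` from effort onset
#' to peak; and `delta_paw_dyn = max(Paw) - set PEEP`. For occluded breaths
#' `delta_pocc = min(Paw) - set PEEP` (<= 0) and flow-derived fields are 0.
#'
#' The Pes/PL baseline is taken at the last pre-inspiratory local maximum
#' of conditioned Pes within `onset_window` seconds before flow onset,
#' capturing effort that begins before the ventilator triggers. Extrema and
#' integrals are computed on the conditioned channels of
#' [preprocess_channels()]; raw channels are never modified.
#'
#' @param rec A [as_recording()] object (or the output of
#'   [preprocess_channels()], which is then reused as-is).
#' @param breaths Breath table from [segment_breaths()] +
#'   [detect_occlusions()].
#' @param ecw Chest-wall elastance, cm H2O/L; default predicts it from the
#'   recording metadata demographics.
#' @param set_peep Set PEEP, cm H2O; default from metadata.
#' @param lowpass_hz,remove_cardiac Channel conditioning, see
#'   [preprocess_channels()].
#' @param onset_window Pre-inspiratory search window for the effort onset, s.
#' @return A tibble with one row per breath: `breath`, `occluded`,
#'   `delta_paw_dyn`, `delta_pes`, `tidal_volume`, `pcw_ei`, `pmus_peak`,
#'   `ptp_mus`, `delta_pl_dyn`, `delta_pocc`, `edi_peak`.
#' @export
breath_metrics <- function(rec, breaths, ecw = NULL, set_peep = NULL,
                           lowpass_hz = 5, remove_cardiac = TRUE,
                           onset_window = 0.3) {
  meta <- rec_meta(rec)
  if (is.null(set_peep)) set_peep <- meta$peep
  if (is.null(set_peep)) {
    abort("set PEEP must be supplied (argument `set_peep` or metadata `peep`)")
  }
  if (is.null(ecw)) {
    ecw <- predicted_chest_wall_elastance(meta$sex, meta$height_cm)
  }
  check_number(ecw, "ecw", 0, allow_equal_lower = FALSE)
  if (nrow(breaths) == 0) {
    abort("empty breath table: segment the recording first")
  }

  fs <- rec_rate(rec)
  dt <- 1 / fs
  pre <- if (all(c("paw_f", "pes_f", "pl_f") %in% names(rec))) rec else
    preprocess_channels(rec, lowpass_hz, remove_cardiac)
  paw_f <- pre$paw_f; pes_f <- pre$pes_f; pl_f <- pre$pl_f
  pes_lp <- if ("pes_lp" %in% names(pre)) pre$pes_lp else pre$pes_f
  edi <- if ("edi" %in% names(rec)) rec$edi else NULL
  w <- round(onset_window * fs)

  nb <- nrow(breaths)
  cols <- list(
    delta_paw_dyn = numeric(nb), delta_pes = numeric(nb),
    tidal_volume = numeric(nb), pcw_ei = numeric(nb),
    pmus_peak = numeric(nb), ptp_mus = numeric(nb),
    delta_pl_dyn = numeric(nb), delta_pocc = rep(NA_real_, nb),
    edi_peak = rep(NA_real_, nb)
  )
  starts <- breaths$start; insp_ends <- breaths$insp_end
  ends <- breaths$end; occl_flags <- breaths$occluded

  for (j in seq_len(nb)) {
    s <- starts[j]; ie <- insp_ends[j]; e <- ends[j]
    if (ie <= s || e <= ie) abort("invalid breath span (empty phase)")
    span <- s:(e - 1)

    # Effort onset: last local maximum of conditioned Pes in the window
    # before flow onset; fall back to the onset sample itself.
    w0 <- max(1, s - w)
    onset <- s
    if (s - w0 >= 2) {
      win <- w0:s
      pw <- pes_f[win]
      k <- length(pw)
      loc <- which(pw[2:(k - 1)] >= pw[1:(k - 2)] &
                     pw[2:(k - 1)] >= pw[3:k]) + 1
      if (length(loc) > 0) onset <- win[max(loc)]
    }
    pes_base <- pes_f[onset]
    pl_base <- pl_f[onset]
    if (!is.null(edi)) cols$edi_peak[j] <- max(edi[span])

    if (occl_flags[j]) {
      # Quasi-static swing on the low-pass-only channel, baseline re-taken
      # on the same channel.
      base_lp <- pes_lp[onset]
      if (s - w0 >= 2) {
        win <- w0:s
        pw <- pes_lp[win]
        k <- length(pw)
        loc <- which(pw[2:(k - 1)] >= pw[1:(k - 2)] &
                       pw[2:(k - 1)] >= pw[3:k]) + 1
        base_lp <- if (length(loc) > 0) pes_lp[win[max(loc)]] else pes_lp[s]
      }
      cols$delta_pes[j] <- min(pes_lp[span]) - base_lp
      cols$delta_pocc[j] <- min(paw_f[span]) - set_peep
      next
    }

    flow_b <- rec$flow[span]
    dur <- (length(span) - 1) * dt
    drift <- trapz(flow_b, dt) / dur
    vol <- cumtrapz(flow_b - drift, dt)
    insp_pos <- seq_len(ie - s)
    vt <- vol[ie - s]
    pes_rel <- pes_f[span] - pes_base
    pmus_t <- ecw * vol - pes_rel
    cols$delta_paw_dyn[j] <- max(paw_f[s:(ie - 1)]) - set_peep
    cols$delta_pes[j] <- min(pes_rel[insp_pos])
    cols$tidal_volume[j] <- vt
    cols$pcw_ei[j] <- ecw * vt
    cols$pmus_peak[j] <- max(pmus_t[insp_pos])
    cols$ptp_mus[j] <- trapz(pmax(pmus_t[insp_pos], 0), dt)
    cols$delta_pl_dyn[j] <- max(pl_f[s:(ie - 1)]) - pl_base
  }

  out <- as_tibble(c(list(breath = breaths$breath, occluded = occl_flags),
                     cols))
  attr(out, "meta") <- meta
  attr(out, "ecw") <- ecw
  attr(out, "set_peep") <- set_peep
  out
}
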