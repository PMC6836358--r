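# Waveform simulator: single-compartment respiratory mechanics driven by a
# raised-cosine muscle-pressure profile, with ventilator triggering/cycling
# and randomly interleaved one-way end-expiratory occlusions.

# Raised-cosine effort profile on [0, 1], peaking (value 1) at `f`.
effort_profile <- function(x, f = 0.5) {
  out <- numeric(length(x))
  up <- x >= 0 & x < f
  down <- x >= f & x <= 1
  out[up] <- 0.5 * (1 - cos(pi * x[up] / f))
  out[down] <- 0.5 * (1 + cos(pi * (x[down] - f) / (1 - f)))
  out
}

#' Simulate one multi-channel ventilator recording
#'
#' Integrates the single-compartment equation of motion
#' `Paw + Pmus = PEEP + Ers * V + R * V'` with a fixed-step explicit scheme
#' at the sampling rate. Each breath is driven by a smooth raised-cosine
#' quasi-static effort waveform whose per-breath amplitude is drawn at
#' random; on flowing breaths the applied muscle pressure is the
#' quasi-static profile scaled by `dynamic_attenuation` (force-velocity
#' effect), while on occluded breaths the one-way valve permits no
#' inspiratory flow, volume is held at the end-expiratory level, and the
#' full quasi-static effort is inscribed on airway pressure as
#' `Paw = PEEP - effort(t)`. Esophageal pressure is built as baseline +
#' chest-wall recoil - applied effort, then scaled by the calibration error
#' and corrupted with a sinusoidal cardiac oscillation plus Gaussian noise.
#' Edi follows the unattenuated quasi-static profile, so neural drive is
#' identical between occluded and non-occluded breaths.
#'
#' @param mechanics A [patient_mechanics()] object.
#' @param vent A [vent_settings()] object.
#' @param config A [sim_config()] object.
#' @param patient,day Identifiers stored in the recording metadata.
#'
#' @return A [as_recording()] tibble with channels `time`, `flow`, `paw`,
#'   `pes`, `edi`, metadata (patient, day, set PEEP, mode, demographics) and
#'   a per-breath ground-truth table retrievable with [rec_truth()].
#' @examples
#' rec <- simulate_recording(
#'   patient_mechanics(), vent_settings(),
#'   sim_config(duration = 60, n_occlusions = 2, seed = 1)
#' )
#' rec_truth(rec)
#' @export
simulate_recording <- function(mechanics, vent, config,
                               patient = "P1", day = 1L) {
  stopifnot(inherits(mechanics, "pocc_mechanics"),
            inherits(vent, "pocc_vent"),
            inherits(config, "pocc_simconfig"))
  if (!is.null(config$seed)) set.seed(config$seed)

  m <- mechanics; v <- vent; cfg <- config
  fs <- cfg$sampling_rate
  dt <- 1 / fs
  n <- round(cfg$duration * fs)
  tvec <- (seq_len(n) - 1) * dt
  ers <- m$lung_elastance + m$chest_wall_elastance
  rr_period <- 60 / m$respiratory_rate
  ti <- m$neural_insp_time
  att <- m$dynamic_attenuation

  # Neural breath onsets with fractional timing jitter.
  onsets <- numeric(0)
  t_on <- 0.2
  while (t_on < cfg$duration - dt) {
    onsets <- c(onsets, t_on)
    jit <- if (cfg$timing_jitter > 0) rnorm(1, 0, cfg$timing_jitter) else 0
    t_on <- t_on + rr_period * max(0.5, 1 + jit)
  }
  k_breaths <- length(onsets)
  amps <- rnorm_trunc(k_breaths, m$effort_amplitude_mean,
                      m$effort_amplitude_sd_within, lower = 0)

  # Occlusions on randomly chosen eligible breaths (complete effort window,
  # not first or last breath).
  next_onset <- c(onsets[-1], cfg$duration)
  eligible <- which(
    seq_len(k_breaths) > 1 & seq_len(k_breaths) < k_breaths &
      onsets + ti < next_onset
  )
  if (cfg$n_occlusions > length(eligible)) {
    abort(sprintf(
      "n_occlusions (%d) exceeds the number of eligible breaths (%d)",
      cfg$n_occlusions, length(eligible)
    ))
  }
  occluded <- rep(FALSE, k_breaths)
  if (cfg$n_occlusions > 0) {
    occluded[sample(eligible, cfg$n_occlusions)] <- TRUE
  }

  # Per-sample quasi-static effort and occlusion-window masks (vectorized).
  breath_of <- findInterval(tvec, onsets)
  xph <- rep(-1, n)
  in_breath <- breath_of > 0
  xph[in_breath] <- (tvec[in_breath] - onsets[breath_of[in_breath]]) / ti
  active <- xph >= 0 & xph <= 1
  e_qs <- numeric(n)
  e_qs[active] <- amps[breath_of[active]] *
    effort_profile(xph[active], cfg$peak_fraction)
  occl_window <- active & occluded[pmax(breath_of, 1)] & in_breath

  # State-machine integration.
  flow <- numeric(n); paw <- numeric(n); vol <- numeric(n)
  V <- 0
  phase_insp <- FALSE
  t0 <- -Inf; peakflow <- 0; V0 <- 0
  last_trig_breath <- 0L
  last_insp_start <- -Inf
  V_hold <- 0; was_occl <- FALSE
  mode <- v$mode
  backup_period <- 60 / v$backup_rate
  Rrs <- m$resistance

  for (i in seq_len(n)) {
    t <- tvec[i]
    e <- e_qs[i]
    if (occl_window[i]) {
      if (!was_occl) V_hold <- V
      was_occl <- TRUE
      phase_insp <- FALSE
      V <- V_hold
      flow[i] <- 0
      paw[i] <- v$peep - e
      vol[i] <- V
      next
    }
    was_occl <- FALSE
    pmus <- att * e
    k <- breath_of[i]
    if (!phase_insp) {
      f_i <- (pmus - ers * V) / Rrs
      trig <- (f_i >= v$trigger_flow_threshold && k > last_trig_breath &&
                 k > 0 && !occluded[k]) ||
        (mode != "PSV" && t - last_insp_start >= backup_period)
      if (trig) {
        phase_insp <- TRUE
        t0 <- t; peakflow <- 0; V0 <- V
        if (k > 0) last_trig_breath <- k
        last_insp_start <- t
      } else {
        flow[i] <- f_i
        paw[i] <- v$peep
        V <- V + f_i * dt
        vol[i] <- V
        next
      }
    }
    # Inspiratory phase.
    tau <- t - t0
    if (mode == "VCV") {
      f_i <- v$set_flow
      p_i <- v$peep + ers * V + Rrs * f_i - pmus
      if (V - V0 >= v$set_tidal_volume) phase_insp <- FALSE
    } else {
      p_i <- v$peep + v$support_level * (1 - exp(-tau / v$rise_time))
      f_i <- (p_i + pmus - v$peep - ers * V) / Rrs
      if (f_i > peakflow) peakflow <- f_i
      cycled <- (mode == "PSV" && tau > 0.2 &&
                   f_i <= v$cycle_fraction * peakflow) ||
        (mode == "PCV" && tau >= v$set_insp_time) ||
        (tau > 0.06 && f_i < 0) || tau > 3
      if (cycled) phase_insp <- FALSE
    }
    flow[i] <- f_i
    paw[i] <- p_i
    V <- V + f_i * dt
    vol[i] <- V
  }

  # Channel assembly.
  e_applied <- ifelse(occl_window, e_qs, att * e_qs)
  pes_clean <- m$pes_baseline + m$chest_wall_elastance * vol - e_applied
  cardiac_phase <- runif(1, 0, 2 * pi)
  cardiac <- cfg$cardiac_artifact_amplitude *
    sin(2 * pi * cfg$cardiac_rate / 60 * tvec + cardiac_phase)
  paw_out <- paw + rnorm(n, 0, cfg$noise_sd)
  pes_out <- m$pes_gain_error * pes_clean + cardiac +
    rnorm(n, 0, cfg$noise_sd)
  edi <- m$edi_gain * e_qs + rnorm(n, 0, cfg$edi_noise_sd)

  # Per-breath ground truth from the clean (gain-1, artifact-free) signals.
  pl_clean <- paw - pes_clean
  onset_idx <- pmin(floor(onsets * fs) + 1, n)
  complete <- onsets + ti < next_onset & next_onset <= cfg$duration
  truth <- tibble(
    breath = seq_len(k_breaths),
    onset_time = onsets,
    onset_idx = as.integer(onset_idx),
    occluded = occluded,
    complete = complete,
    amplitude = amps,
    attenuation = att,
    pmus_true_peak = ifelse(occluded, amps, att * amps),
    delta_pocc_true = ifelse(occluded, -amps, NA_real_),
    # Raised-cosine profile integrates to ti/2 exactly.
    ptp_true = ifelse(occluded, 0, att * amps * ti / 2)
  )
  span_stat <- function(k, f) {
    i0 <- onset_idx[k]
    i1 <- min(n, floor(next_onset[k] * fs))
    f(i0:i1, i0)
  }
  truth$vt_true <- vapply(seq_len(k_breaths), function(k) {
    if (occluded[k]) return(0)
    span_stat(k, function(sp, i0) max(vol[sp]) - vol[i0])
  }, numeric(1))
  truth$delta_pes_true <- vapply(seq_len(k_breaths), function(k) {
    span_stat(k, function(sp, i0) min(pes_clean[sp]) - pes_clean[i0])
  }, numeric(1))
  truth$delta_pl_dyn_true <- vapply(seq_len(k_breaths), function(k) {
    if (occluded[k]) return(NA_real_)
    span_stat(k, function(sp, i0) max(pl_clean[sp]) - pl_clean[i0])
  }, numeric(1))

  rec <- as_recording(
    tibble(time = tvec, flow = flow, paw = paw_out, pes = pes_out,
           edi = edi),
    sampling_rate = fs,
    meta = list(
      patient = patient, day = day, peep = v$peep, mode = v$mode,
      sex = m$sex, height_cm = m$height_cm
    )
  )
  attr(rec, "truth") <- truth
  rec
}
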