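# Signal conditioning before extremum extraction: zero-phase low-pass for
# wideband noise, and narrowband subtraction of the cardiac oscillation,
# which lies inside the effort band and therefore cannot be removed by any
# effort-preserving low-pass.

# Zero-phase Butterworth low-pass (order 4), applied forward and backward.
lowpass <- function(x, fs, cutoff_hz = 5) {
  if (is.null(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2) return(x)
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Estimate and subtract the dominant cardiac tone from Pes.
#
# The tone is located as the periodogram peak in the cardiac band
# (0.75-3 Hz), refined by maximizing the sinusoid-regression fit, and
# accepted only if the fitted sinusoid is coherent across the two halves of
# the recording (amplitude > `min_amplitude` in both halves, phase
# agreement < 0.8 rad). Respiratory harmonics decohere over minutes because
# breath timing is not metronomic, so the guard rejects them; a genuine
# cardiac oscillation is near-stationary and passes.
suppress_cardiac <- function(x, fs, band = c(0.75, 3),
                             min_amplitude = 0.25) {
  n <- length(x)
  if (n < fs * 20) {
    return(list(x = x, removed = FALSE, freq = NA_real_,
                amplitude = NA_real_))
  }
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = TRUE, plot = FALSE)
  # Locate the respiratory fundamental (dominant line below 0.7 Hz) and
  # mask neighborhoods of its harmonics: effort energy concentrates there
  # and must never be mistaken for the cardiac tone. Windows widen with
  # harmonic number because timing jitter broadens higher harmonics.
  in_band <- sp$freq >= band[1] & sp$freq <= band[2]
  resp_band <- sp$freq >= 0.1 & sp$freq < 0.7
  if (any(resp_band)) {
    f_resp <- sp$freq[resp_band][which.max(sp$spec[resp_band])]
    for (m in 2:10) {
      fm <- m * f_resp
      if (fm > band[2] + 0.3) break
      in_band <- in_band & abs(sp$freq - fm) > 0.05 + 0.025 * m
    }
  }
  if (!any(in_band)) {
    return(list(x = x, removed = FALSE, freq = NA_real_,
                amplitude = NA_real_))
  }
  f0 <- sp$freq[in_band][which.max(sp$spec[in_band])]

  tvec <- (seq_len(n) - 1) / fs
  fit_at <- function(f, idx) {
    s <- sin(2 * pi * f * tvec[idx]); c_ <- cos(2 * pi * f * tvec[idx])
    co <- stats::coef(stats::lm.fit(cbind(1, s, c_), x[idx]))
    list(a = sqrt(co[2]^2 + co[3]^2), phase = atan2(co[3], co[2]),
         coef = co)
  }
  rss_at <- function(f) {
    s <- sin(2 * pi * f * tvec); c_ <- cos(2 * pi * f * tvec)
    sum(stats::lm.fit(cbind(1, s, c_), x)$residuals^2)
  }
  df <- 1 / (n / fs)
  opt <- optimize(rss_at, interval = c(f0 - df, f0 + df))
  f_hat <- opt$minimum

  half <- seq_len(floor(n / 2))
  fit1 <- fit_at(f_hat, half)
  fit2 <- fit_at(f_hat, (floor(n / 2) + 1):n)
  dphase <- abs(atan2(sin(fit1$phase - fit2$phase),
                      cos(fit1$phase - fit2$phase)))
  coherent <- fit1$a > min_amplitude && fit2$a > min_amplitude &&
    dphase < 0.8
  if (!coherent) {
    return(list(x = x, removed = FALSE, freq = f_hat,
                amplitude = NA_real_))
  }
  full <- fit_at(f_hat, seq_len(n))
  tone <- full$coef[1] * 0 + full$coef[2] * sin(2 * pi * f_hat * tvec) +
    full$coef[3] * cos(2 * pi * f_hat * tvec)
  list(x = x - tone, removed = TRUE, freq = f_hat, amplitude = full$a)
}

#' Condition the pressure channels of a recording
#'
#' Returns the recording with additional columns `paw_f`, `pes_lp`,
#' `pes_f` and `pl_f` (transpulmonary pressure Paw - Pes): airway and
#' esophageal pressure after a zero-phase low-pass at `lowpass_hz`
#' (`pes_lp`), with the dominant cardiac tone additionally subtracted from
#' Pes (`pes_f`) when `remove_cardiac = TRUE` and a coherent tone is found.
#' Raw channels are never overwritten. Per-breath metrics
#' ([breath_metrics()]) take dynamic-breath extrema and integrals from the
#' tone-suppressed channel, but quasi-static (occluded-breath) swings from
#' the low-pass-only channel: those swings are large relative to the
#' artifact, and an imperfect tone fit would bias them more than the
#' artifact itself does.
#'
#' @param rec A [as_recording()] object.
#' @param lowpass_hz Low-pass cutoff in Hz, or `NULL` to disable.
#' @param remove_cardiac Subtract the estimated cardiac tone from Pes.
#' @return The input tibble with columns `paw_f`, `pes_f`, `pl_f` appended
#'   and an attribute `cardiac` describing the fitted tone.
#' @export
preprocess_channels <- function(rec, lowpass_hz = 5, remove_cardiac = TRUE) {
  fs <- rec_rate(rec)
  paw_f <- lowpass(rec$paw, fs, lowpass_hz)
  pes_lp <- lowpass(rec$pes, fs, lowpass_hz)
  card <- if (remove_cardiac) {
    suppress_cardiac(pes_lp, fs)
  } else {
    list(x = pes_lp, removed = FALSE, freq = NA_real_, amplitude = NA_real_)
  }
  pes_f <- card$x
  out <- mutate(as_tibble(rec), paw_f = paw_f, pes_lp = pes_lp,
                pes_f = pes_f, pl_f = paw_f - pes_f)
  out <- structure(out, class = class(rec),
                   sampling_rate = fs, meta = rec_meta(rec),
                   truth = rec_truth(rec))
  attr(out, "cardiac") <- card[c("removed", "freq", "amplitude")]
  out
}
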