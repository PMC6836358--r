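# Per-breath reference metrics: closed-form constructions, oracle
# equivalence, and agreement with simulator ground truth.

test_that("transpulmonary pressure is the samplewise difference", {
  expect_equal(transpulmonary(c(5, 5), c(5, 5)), c(0, 0))
  expect_equal(transpulmonary(10, -8), 18)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(transpulmonary(x + 3, y + 3), transpulmonary(x, y))
  expect_error(transpulmonary(1:3, 1:2), "same length")
})

# A constructed breath with synchronous linear ramps:
# flow +0.4 L/s for 1 s then -0.4 L/s (Vt = 0.4 L), Pes falling linearly
# to -8 at end-inspiration, Paw rising linearly by 3.
make_ramp_breath <- function() {
  fs <- 100
  n <- 5 * fs
  tvec <- (0:(n - 1)) / fs
  flow <- numeric(n); pes <- numeric(n); paw <- rep(5, n)
  i_in <- which(tvec >= 1 & tvec < 2)
  i_ex <- which(tvec >= 2 & tvec < 3)
  flow[i_in] <- 0.4; flow[i_ex] <- -0.4
  ramp <- seq_along(i_in) / length(i_in)
  pes[i_in] <- -8 * ramp
  pes[i_ex] <- -8 * rev(ramp)
  paw[i_in] <- 5 + 3 * ramp
  rec <- as_recording(
    tibble::tibble(time = tvec, flow = flow, paw = paw, pes = pes),
    meta = list(peep = 5)
  )
  breaths <- tibble::tibble(breath = 1L, start = i_in[1],
                            insp_end = i_ex[1], end = i_ex[length(i_ex)] + 1L,
                            occluded = FALSE)
  list(rec = rec, breaths = breaths)
}

test_that("closed-form construction recovers Pcw, delta-Pes, Pmus and PTP", {
  b <- make_ramp_breath()
  m <- breath_metrics(b$rec, b$breaths, ecw = 5, set_peep = 5,
                      lowpass_hz = NULL, remove_cardiac = FALSE)
  expect_equal(m$tidal_volume, 0.4, tolerance = 0.02)
  expect_equal(m$pcw_ei, 2.0, tolerance = 0.02)
  expect_equal(m$delta_pes, -8, tolerance = 0.01)
  expect_equal(m$pmus_peak, 10, tolerance = 0.02)
  # Pmus(t) = (Ecw*V + |Pes|)(t) = 10 t: triangle of peak 10 over 1 s.
  expect_equal(m$ptp_mus, 5, tolerance = 0.02)
  expect_equal(m$delta_paw_dyn, 3, tolerance = 0.01)
  # Synchronous-extrema limit: dPL,dyn = dPaw,dyn - dPes exactly.
  expect_equal(m$delta_pl_dyn, m$delta_paw_dyn - m$delta_pes,
               tolerance = 1e-9)
})

test_that("package metrics equal the brute-force oracle to 1e-9", {
  an <- default_analysis()
  oracle <- oracle_breath_metrics(default_rec(), an$breaths,
                                  ecw = attr(an$metrics, "ecw"),
                                  set_peep = 8)
  got <- an$metrics[, names(oracle)]
  for (col in setdiff(names(oracle), c("breath", "occluded"))) {
    expect_equal(got[[col]], oracle[[col]], tolerance = 1e-9,
                 label = col)
  }
})

test_that("Pmus peak and PTP match simulator ground truth within 2%", {
  rec <- simulate_recording(
    patient_mechanics(), vent_settings(),
    sim_config(duration = 150, n_occlusions = 4, noise_sd = 0,
               cardiac_artifact_amplitude = 0, seed = 21)
  )
  tr <- rec_truth(rec)
  an <- suppressMessages(analyze_recording(rec, ecw = 5,
                                           remove_cardiac = FALSE))
  met <- an$metrics[!an$metrics$occluded, ]
  br <- an$breaths[!an$breaths$occluded, ]
  fs <- rec_rate(rec)

  # Match each detected breath to the simulated breath whose onset is
  # closest to its start sample.
  fl <- tr[!tr$occluded & tr$complete, ]
  match_idx <- vapply(br$start, function(s) {
    which.min(abs(fl$onset_idx - s))
  }, integer(1))
  n <- min(nrow(met), 50)
  expect_gte(n, 40)
  checked <- 0
  for (i in seq_len(n)) {
    k <- match_idx[i]
    if (abs(fl$onset_idx[k] - br$start[i]) > 0.5 * fs) next
    expect_lt(abs(met$pmus_peak[i] / fl$pmus_true_peak[k] - 1), 0.02)
    # Brute-force trapezoid of the true attenuated effort over the same
    # inspiratory window (raised-cosine profile, peak at half the neural
    # inspiratory time).
    tt <- rec$time[br$start[i]:(br$insp_end[i] - 1)] - fl$onset_time[k]
    x <- tt / 0.9
    prof <- ifelse(x >= 0 & x < 0.5, 0.5 * (1 - cos(pi * x / 0.5)),
                   ifelse(x >= 0.5 & x <= 1,
                          0.5 * (1 + cos(pi * (x - 0.5) / 0.5)), 0))
    true_eff <- fl$attenuation[k] * fl$amplitude[k] * prof
    true_ptp <- loop_trapz(true_eff, 1 / fs)
    expect_lt(abs(met$ptp_mus[i] / true_ptp - 1), 0.02)
    checked <- checked + 1
  }
  expect_gte(checked, 40)
})

test_that("predicted chest-wall elastance is calibrated and monotone", {
  expect_equal(predicted_chest_wall_elastance("male", 175), 5.0)
  h <- seq(150, 200, by = 5)
  e_m <- vapply(h, function(x) predicted_chest_wall_elastance("male", x),
                numeric(1))
  expect_true(all(diff(e_m) < 0))
  expect_message(
    out <- predicted_chest_wall_elastance(ecw_override = 6.2),
    "6.2"
  )
  expect_equal(out, 6.2)
  expect_error(predicted_chest_wall_elastance(), "ecw_override")
})

test_that("passive breaths have near-zero Pmus; effort breaths have dPL > dPaw", {
  rec <- simulate_recording(
    patient_mechanics(effort_amplitude_mean = 0,
                      effort_amplitude_sd_within = 0,
                      lung_elastance = 20),
    vent_settings(mode = "PCV", support_level = 10, backup_rate = 14),
    sim_config(duration = 60, n_occlusions = 0, noise_sd = 0,
               cardiac_artifact_amplitude = 0, seed = 6)
  )
  an <- suppressWarnings(suppressMessages(
    analyze_recording(rec, ecw = 5, remove_cardiac = FALSE)
  ))
  expect_true(all(abs(an$metrics$pmus_peak) < 0.1))

  eff <- clean_analysis()$metrics
  eff <- eff[!eff$occluded, ]
  expect_true(all(eff$delta_pl_dyn > eff$delta_paw_dyn))
  expect_true(all(eff$delta_pes < 0))
})

test_that("validity ratio classifies calibration errors, inclusive at the bounds", {
  base <- tibble::tibble(
    breath = 1:4, occluded = c(FALSE, TRUE, FALSE, TRUE),
    delta_paw_dyn = 5, delta_pes = c(-10, -10, -10, -10),
    tidal_volume = 0.4, pcw_ei = 2, pmus_peak = 12, ptp_mus = 5,
    delta_pl_dyn = 15, delta_pocc = c(NA, -10, NA, -10), edi_peak = 10
  )
  attr(base, "meta") <- list(patient = "X", day = 1)
  s <- summarize_recording(base)
  expect_equal(s$pocc_pes_ratio, 1)
  expect_true(s$valid)

  # Ratio exactly at the lower bound is still valid (inclusive band).
  b2 <- base; b2$delta_pocc <- c(NA, -7, NA, -7)
  attr(b2, "meta") <- list(patient = "X", day = 1)
  expect_true(summarize_recording(b2)$valid)
  b3 <- base; b3$delta_pocc <- c(NA, -6.9, NA, -6.9)
  attr(b3, "meta") <- list(patient = "X", day = 1)
  expect_false(summarize_recording(b3)$valid)

  # A 1.6x Pes gain pushes the ratio to ~1/1.6 and excludes the recording.
  rec <- simulate_recording(
    patient_mechanics(pes_gain_error = 1.6), vent_settings(),
    sim_config(duration = 45, n_occlusions = 3, noise_sd = 0,
               cardiac_artifact_amplitude = 0, seed = 4)
  )
  s2 <- suppressMessages(analyze_recording(rec, remove_cardiac = FALSE))$summary
  expect_equal(s2$pocc_pes_ratio, 1 / 1.6, tolerance = 0.03)
  expect_false(s2$valid)

  # No occlusions: undefined ratio, invalid, warned.
  b4 <- base[!base$occluded, ]
  attr(b4, "meta") <- list(patient = "X", day = 1)
  expect_warning(s4 <- summarize_recording(b4), "no occlusions")
  expect_false(s4$valid)
})

test_that("Edi drive check detects a doubled occluded-breath drive", {
  met <- tibble::tibble(
    breath = 1:9,
    occluded = rep(c(FALSE, FALSE, TRUE), 3),
    edi_peak = rep(c(10, 10, 20), 3)
  )
  ed <- edi_drive_check(met)
  expect_equal(ed$mean_diff, 10)

  met$edi_peak <- NA_real_
  expect_message(out <- edi_drive_check(met), "skipped")
  expect_null(out)

  met2 <- tibble::tibble(breath = 1:3, occluded = c(FALSE, TRUE, FALSE),
                         edi_peak = c(10, 10, 10))
  expect_error(edi_drive_check(met2), "at least 3")
})
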