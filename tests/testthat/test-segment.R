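# Breath segmentation and occlusion detection against simulator truth.

test_that("detected breath count matches the simulator log on a 10-min recording", {
  rec <- simulate_recording(
    patient_mechanics(respiratory_rate = 20), vent_settings(),
    sim_config(duration = 600, n_occlusions = 15, seed = 13)
  )
  breaths <- suppressMessages(
    detect_occlusions(rec, segment_breaths(rec))
  )
  expected <- sum(rec_truth(rec)$complete)
  expect_lte(abs(nrow(breaths) - expected), 2)
  expect_equal(sum(breaths$occluded), 15)
})

test_that("a flat recording yields no breaths, with a warning", {
  n <- 2000
  flat <- as_recording(
    tibble::tibble(time = (0:(n - 1)) / 100, flow = 0, paw = 8, pes = 5),
    meta = list(peep = 8)
  )
  expect_warning(b <- segment_breaths(flat), "no complete breaths")
  expect_equal(nrow(b), 0)
})

test_that("a final partial breath is discarded", {
  rec <- default_rec()
  breaths <- segment_breaths(rec)
  # Truncate in the middle of the last detected inspiration.
  cut <- breaths$insp_end[nrow(breaths)] - 2
  part <- as_recording(tibble::as_tibble(rec)[1:cut, ],
                       sampling_rate = rec_rate(rec),
                       meta = rec_meta(rec))
  b2 <- segment_breaths(part)
  expect_equal(nrow(b2), nrow(breaths) - 1)
  expect_true(all(b2$end <= cut))
})

test_that("flagged occlusions equal the scheduled set under default noise", {
  for (s in 1:10) {
    rec <- simulate_recording(
      patient_mechanics(), vent_settings(),
      sim_config(duration = 90, n_occlusions = 4, seed = 100 + s)
    )
    breaths <- suppressMessages(
      detect_occlusions(rec, segment_breaths(rec))
    )
    occ_starts <- breaths$start[breaths$occluded]
    sched <- rec_truth(rec)$onset_idx[rec_truth(rec)$occluded]
    expect_equal(length(occ_starts), length(sched))
    # Each flagged episode begins within 250 ms of a scheduled onset.
    expect_true(all(vapply(occ_starts, function(s0) {
      min(abs(s0 - sched)) < 25
    }, logical(1))))
  }
})

test_that("a passive recording has no flagged occlusions", {
  rec <- simulate_recording(
    patient_mechanics(effort_amplitude_mean = 0,
                      effort_amplitude_sd_within = 0),
    vent_settings(mode = "PCV", backup_rate = 14),
    sim_config(duration = 60, n_occlusions = 0, seed = 8)
  )
  breaths <- suppressMessages(detect_occlusions(rec, segment_breaths(rec)))
  expect_equal(sum(breaths$occluded), 0)
})

test_that("sub-threshold deflections are logged but not flagged", {
  # Constructed trace: two flow breaths around a 0.8 cm H2O no-flow dip.
  fs <- 100
  n <- 12 * fs
  tvec <- (0:(n - 1)) / fs
  flow <- numeric(n); paw <- rep(8, n); pes <- rep(5, n)
  insp <- function(t0) which(tvec >= t0 & tvec < t0 + 1)
  for (t0 in c(1, 9)) {
    idx <- insp(t0)
    flow[idx] <- 0.5 * sin(pi * seq_along(idx) / length(idx))
    flow[idx + length(idx)] <- -0.4 * sin(pi * seq_along(idx) / length(idx))
    paw[idx] <- 8 + 6 * sin(pi * seq_along(idx) / length(idx))
  }
  dip <- which(tvec >= 5 & tvec < 6)
  paw[dip] <- 8 - 0.8 * sin(pi * seq_along(dip) / length(dip))
  rec <- as_recording(
    tibble::tibble(time = tvec, flow = flow, paw = paw, pes = pes),
    meta = list(peep = 8)
  )
  breaths <- segment_breaths(rec)
  expect_message(
    out <- detect_occlusions(rec, breaths, deflection_threshold = 1),
    "sub-threshold"
  )
  expect_equal(sum(out$occluded), 0)
})
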