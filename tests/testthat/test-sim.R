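# Simulator physics and cohort structure.

test_that("passive pressure-control breath reaches the elastance-determined tidal volume", {
  m <- patient_mechanics(
    lung_elastance = 20, chest_wall_elastance = 5, resistance = 10,
    effort_amplitude_mean = 0, effort_amplitude_sd_within = 0,
    respiratory_rate = 12
  )
  v <- vent_settings(mode = "PCV", support_level = 10, set_insp_time = 2.5,
                     backup_rate = 10)
  rec <- simulate_recording(m, v, sim_config(
    duration = 60, n_occlusions = 0, noise_sd = 0,
    cardiac_artifact_amplitude = 0, timing_jitter = 0, seed = 1
  ))
  vol <- cumsum(rec$flow) / rec_rate(rec)
  # Long inspiration: volume approaches support / Ers = 10/25 = 0.4 L.
  expect_equal(max(vol), 0.4, tolerance = 0.02)
  # Passive Pes swing equals chest-wall recoil Ecw * Vt.
  expect_equal(max(rec$pes) - min(rec$pes), 5 * max(vol), tolerance = 0.01)
})

test_that("occluded breaths inscribe the quasi-static effort on airway pressure", {
  rec <- clean_rec()
  tr <- rec_truth(rec)
  occ <- tr[tr$occluded, ]
  fs <- rec_rate(rec)
  ti <- 0.9
  for (i in seq_len(nrow(occ))) {
    span <- occ$onset_idx[i]:(occ$onset_idx[i] + round(ti * fs))
    # Maximal deflection below PEEP equals the quasi-static amplitude.
    expect_equal(min(rec$paw[span]) , 8 - occ$amplitude[i],
                 tolerance = 0.01 * occ$amplitude[i] / 8)
    # No inspiratory flow during the attempt (strictly inside the window).
    inner <- span[3:(length(span) - 2)]
    expect_true(all(rec$flow[inner] == 0))
  }
})

test_that("identical seeds reproduce bit-identical channels", {
  cfg <- sim_config(duration = 30, n_occlusions = 2, seed = 42)
  r1 <- simulate_recording(patient_mechanics(), vent_settings(), cfg)
  r2 <- simulate_recording(patient_mechanics(), vent_settings(), cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(rec_truth(r1), rec_truth(r2))
})

test_that("end-expiratory volume is cyclically stationary under constant effort", {
  rec <- simulate_recording(
    patient_mechanics(effort_amplitude_sd_within = 0),
    vent_settings(),
    sim_config(duration = 60, n_occlusions = 0, noise_sd = 0,
               cardiac_artifact_amplitude = 0, timing_jitter = 0, seed = 3)
  )
  tr <- rec_truth(rec)
  vol <- c(0, cumsum((rec$flow[-1] + rec$flow[-nrow(rec)]) / 2) /
             rec_rate(rec))
  onset_vol <- vol[tr$onset_idx[tr$complete]]
  # Successive end-expiratory volumes settle within 1 mL.
  expect_true(all(abs(diff(onset_vol[-1])) < 1e-3))
})

test_that("peak Edi is invariant to the occlusion maneuver", {
  an <- clean_analysis()
  ed <- edi_drive_check(an$metrics)
  expect_lt(abs(ed$mean_diff), 0.01)
})

test_that("dynamic-to-occlusion swing ratio follows the attenuation identity", {
  tr <- rec_truth(clean_rec())
  fl <- tr[!tr$occluded & tr$complete, ]
  att <- fl$attenuation[1]
  ecw <- 5
  ratio <- abs(fl$delta_pes_true) / fl$amplitude
  # Pes swing ratio lies between att - Ecw*Vt/A (volume at peak effort
  # below Vt) and att itself.
  expect_true(all(ratio <= att + 0.02))
  expect_true(all(ratio >= att - ecw * fl$vt_true / fl$amplitude - 0.02))
})

test_that("invalid simulator configurations are rejected", {
  expect_error(patient_mechanics(effort_amplitude_sd_within = -1),
               "effort_amplitude_sd_within")
  expect_error(patient_mechanics(lung_elastance = NaN), "finite")
  expect_error(patient_mechanics(dynamic_attenuation = 1.2),
               "dynamic_attenuation")
  expect_error(vent_settings(cycle_fraction = 1), "cycle_fraction")
  expect_error(sim_config(sampling_rate = 20), "sampling_rate")
  # More occlusions than eligible breaths.
  expect_error(
    simulate_recording(patient_mechanics(), vent_settings(),
                       sim_config(duration = 20, n_occlusions = 50,
                                  seed = 1)),
    "eligible"
  )
})

test_that("cohorts have the requested structure and per-patient streams", {
  co <- small_cohort()
  expect_length(co$recordings, 16)
  expect_length(unique(co$truth$patient), 8)
  expect_equal(nrow(co$truth), 16)
  # Adding patients does not perturb earlier patients' recordings.
  co2 <- simulate_cohort(9, 2,
                         config = sim_config(duration = 90,
                                             n_occlusions = 4), seed = 31)
  expect_identical(as.data.frame(co$recordings[["P03_d1"]]),
                   as.data.frame(co2$recordings[["P03_d1"]]))
})

test_that("zero within-patient variability gives identical mechanics across days", {
  pop <- cohort_population(effort_sd_day = 0, attenuation_sd_day = 0,
                           rate_sd_day = 0, effort_sd_within = 0)
  co <- simulate_cohort(3, 2, population = pop,
                        config = sim_config(duration = 40, n_occlusions = 2),
                        seed = 5)
  for (p in unique(co$breath_truth$patient)) {
    amps <- unique(round(
      co$breath_truth$amplitude[co$breath_truth$patient == p], 12
    ))
    expect_length(amps, 1)
  }
})

test_that("degenerate population distributions are rejected", {
  expect_error(cohort_population(effort_sd_between = -1),
               "effort_sd_between")
})
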