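# Multi-patient cohort generation: between-patient parameters drawn once
# per patient, within-patient (day-level) parameters per recording.

#' Population distributions for cohort simulation
#'
#' Describes how [simulate_cohort()] draws patient-level mechanics and
#' effort parameters, and how much they vary from day to day within a
#' patient. Defaults emulate a mixed ICU cohort on partially assisted
#' ventilation whose inspiratory effort spans the 10 and 15 cm H2O
#' screening thresholds: quasi-static amplitudes around 20 cm H2O with wide
#' between-patient spread give dynamic Pmus values mostly between 4 and
#' 30 cm H2O.
#'
#' @param effort_mean,effort_sd_between Mean and between-patient SD of the
#'   patient-level quasi-static effort amplitude, cm H2O.
#' @param effort_sd_day Day-to-day (between-recording) SD of the amplitude
#'   within a patient, cm H2O.
#' @param effort_sd_within Breath-to-breath SD within a recording, cm H2O.
#' @param attenuation_mean,attenuation_sd Patient-level mean and SD of the
#'   dynamic attenuation ratio.
#' @param attenuation_sd_day Day-to-day SD of the attenuation.
#' @param lung_elastance_mean,lung_elastance_sd Lung elastance, cm H2O/L.
#' @param resistance_mean,resistance_sd Resistance, cm H2O.s/L.
#' @param insp_time_mean,insp_time_sd Neural inspiratory time, s.
#' @param rate_mean,rate_sd Respiratory rate, breaths/min.
#' @param rate_sd_day Day-to-day SD of the rate.
#' @param edi_gain_mean,edi_gain_sd Edi gain, uV per cm H2O.
#' @param pes_gain_sdlog SD of log pes_gain_error (patient-level
#'   multiplicative esophageal miscalibration).
#' @param ecw_rel_sdlog SD of the log-ratio between a patient's true
#'   chest-wall elastance and the demographics-predicted value.
#' @param p_female Probability that a patient is female.
#' @param height_mean_male,height_mean_female,height_sd Heights, cm.
#'
#' @return A list of class `pocc_population`.
#' @export
cohort_population <- function(effort_mean = 20, effort_sd_between = 8,
                              effort_sd_day = 4, effort_sd_within = 1.5,
                              attenuation_mean = 0.74, attenuation_sd = 0.06,
                              attenuation_sd_day = 0.02,
                              lung_elastance_mean = 15, lung_elastance_sd = 4,
                              resistance_mean = 10, resistance_sd = 3,
                              insp_time_mean = 0.9, insp_time_sd = 0.12,
                              rate_mean = 22, rate_sd = 4, rate_sd_day = 2,
                              edi_gain_mean = 1, edi_gain_sd = 0.3,
                              pes_gain_sdlog = 0.12,
                              ecw_rel_sdlog = 0.08,
                              p_female = 0.44,
                              height_mean_male = 175,
                              height_mean_female = 162,
                              height_sd = 7) {
  pop <- as.list(environment())
  for (nm in names(pop)) {
    is_sd <- grepl("_sd", nm) || grepl("sdlog", nm)
    check_number(pop[[nm]], nm, lower = if (is_sd) 0 else -Inf)
  }
  check_number(p_female, "p_female", 0, 1)
  structure(pop, class = "pocc_population")
}

#' Simulate a multi-patient cohort of daily recordings
#'
#' Patient-level parameters are drawn once per patient from
#' [cohort_population()] distributions; day-level deviations are drawn per
#' recording. Each patient uses a deterministic child seed of `seed`, so
#' increasing `n_patients` does not perturb earlier patients' data.
#'
#' @param n_patients Number of patients (>= 2).
#' @param recordings_per_patient Daily recordings per patient.
#' @param population A [cohort_population()] object.
#' @param vent A [vent_settings()] object shared by all recordings.
#' @param config A [sim_config()] object; its `seed` field is ignored in
#'   favor of per-recording child seeds.
#' @param seed Integer cohort seed.
#' @param patient_overrides Optional named list: entry `"3"` is a list of
#'   [patient_mechanics()] fields forced for patient 3 (used e.g. to inject
#'   a known esophageal miscalibration).
#'
#' @return A list of class `pocc_cohort` with elements `recordings` (named
#'   list of [as_recording()] objects), `truth` (per-recording ground-truth
#'   summary: true mean Pmus, true mean delta-Pocc, true attenuation, true
#'   conversion ratios) and `breath_truth` (per-breath ground truth with
#'   patient/day keys).
#' @export
simulate_cohort <- function(n_patients = 16, recordings_per_patient = 3,
                            population = cohort_population(),
                            vent = vent_settings(),
                            config = sim_config(),
                            seed = 1L,
                            patient_overrides = list()) {
  check_count(n_patients, "n_patients", 2)
  check_count(recordings_per_patient, "recordings_per_patient", 1)
  stopifnot(inherits(population, "pocc_population"),
            inherits(vent, "pocc_vent"),
            inherits(config, "pocc_simconfig"))
  check_count(seed, "seed")
  pop <- population

  recordings <- list()
  truth_rows <- list()
  breath_rows <- list()

  for (p in seq_len(n_patients)) {
    set.seed(child_seed(seed, p))
    sex <- if (runif(1) < pop$p_female) "female" else "male"
    height <- rnorm_trunc(1, if (sex == "male") pop$height_mean_male else
      pop$height_mean_female, pop$height_sd, 140, 210)
    ecw_pred <- predicted_chest_wall_elastance(sex, height)
    pat <- list(
      lung_elastance = rnorm_trunc(1, pop$lung_elastance_mean,
                                   pop$lung_elastance_sd, 6, 35),
      chest_wall_elastance = ecw_pred * exp(rnorm(1, 0, pop$ecw_rel_sdlog)),
      resistance = rnorm_trunc(1, pop$resistance_mean, pop$resistance_sd,
                               4, 25),
      effort_mean = rnorm_trunc(1, pop$effort_mean, pop$effort_sd_between,
                                3, 50),
      attenuation = rnorm_trunc(1, pop$attenuation_mean, pop$attenuation_sd,
                                0.5, 0.95),
      insp_time = rnorm_trunc(1, pop$insp_time_mean, pop$insp_time_sd,
                              0.5, 1.5),
      rate = rnorm_trunc(1, pop$rate_mean, pop$rate_sd, 12, 35),
      edi_gain = rnorm_trunc(1, pop$edi_gain_mean, pop$edi_gain_sd, 0.2, 3),
      pes_gain_error = exp(rnorm(1, 0, pop$pes_gain_sdlog)),
      sex = sex, height_cm = height
    )
    ov <- patient_overrides[[as.character(p)]]

    for (r in seq_len(recordings_per_patient)) {
      # Day-level deviations drawn from the patient stream.
      eff_day <- rnorm_trunc(1, pat$effort_mean, pop$effort_sd_day, 2, 60)
      att_day <- rnorm_trunc(1, pat$attenuation, pop$attenuation_sd_day,
                             0.4, 1)
      rate_day <- rnorm_trunc(1, pat$rate, pop$rate_sd_day, 12, 35)
      mech_args <- list(
        lung_elastance = pat$lung_elastance,
        chest_wall_elastance = pat$chest_wall_elastance,
        resistance = pat$resistance,
        effort_amplitude_mean = eff_day,
        effort_amplitude_sd_within = pop$effort_sd_within,
        neural_insp_time = pat$insp_time,
        respiratory_rate = rate_day,
        dynamic_attenuation = att_day,
        edi_gain = pat$edi_gain,
        pes_gain_error = pat$pes_gain_error,
        sex = pat$sex, height_cm = pat$height_cm
      )
      if (!is.null(ov)) mech_args[names(ov)] <- ov
      mech <- do.call(patient_mechanics, mech_args)
      cfg <- config
      cfg$seed <- child_seed(child_seed(seed, p), 97L + r)
      pid <- sprintf("P%02d", p)
      rec <- simulate_recording(mech, vent, cfg, patient = pid, day = r)
      key <- sprintf("%s_d%d", pid, r)
      recordings[[key]] <- rec

      bt <- rec_truth(rec)
      flowing <- bt$complete & !bt$occluded
      occl <- bt$occluded
      truth_rows[[key]] <- tibble(
        patient = pid, day = r,
        true_mean_pmus = mean(bt$pmus_true_peak[flowing]),
        true_mean_delta_pes = mean(bt$delta_pes_true[flowing]),
        true_mean_delta_pl = mean(bt$delta_pl_dyn_true[flowing]),
        true_mean_pocc = mean(bt$delta_pocc_true[occl]),
        true_attenuation = mech$dynamic_attenuation,
        true_pes_gain_error = mech$pes_gain_error,
        true_ecw = mech$chest_wall_elastance,
        true_k1 = -mean(bt$pmus_true_peak[flowing]) /
          abs(mean(bt$delta_pocc_true[occl])),
        true_k2 = mean(bt$delta_pes_true[flowing]) /
          mean(bt$delta_pocc_true[occl])
      )
      breath_rows[[key]] <- mutate(bt, patient = pid, day = r,
                                   .before = 1)
    }
  }

  structure(
    list(
      recordings = recordings,
      truth = bind_rows(truth_rows),
      breath_truth = bind_rows(breath_rows)
    ),
    class = "pocc_cohort"
  )
}

#' @export
print.pocc_cohort <- function(x, ...) {
  cat(sprintf(
    "<pocc_cohort> %d recordings in %d patients\n",
    length(x$recordings), length(unique(x$truth$patient))
  ))
  invisible(x)
}
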