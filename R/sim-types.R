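#' Patient respiratory mechanics and effort parameters
#'
#' Bundles the single-compartment mechanics and the inspiratory-effort model
#' of one simulated patient. Quasi-static effort amplitude is the peak
#' muscle pressure the patient would inscribe against a closed airway;
#' during flowing breaths the effective amplitude is scaled by
#' `dynamic_attenuation`, reflecting the force-velocity properties of
#' contracting inspiratory muscle (pressure output falls when the muscle is
#' allowed to shorten).
#'
#' @param lung_elastance Lung elastance, cm H2O/L.
#' @param chest_wall_elastance Chest-wall elastance, cm H2O/L.
#' @param resistance Respiratory-system resistance, cm H2O.s/L.
#' @param effort_amplitude_mean Mean quasi-static peak muscle pressure per
#'   breath, cm H2O. Zero simulates a passive patient.
#' @param effort_amplitude_sd_within Breath-to-breath SD of the quasi-static
#'   amplitude, cm H2O.
#' @param neural_insp_time Duration of the neural inspiratory effort, s.
#' @param respiratory_rate Neural respiratory rate, breaths/min.
#' @param dynamic_attenuation Ratio of flowing-breath effort amplitude to
#'   quasi-static amplitude, in (0, 1].
#' @param edi_gain Diaphragm electrical activity per unit of quasi-static
#'   muscle pressure, uV per cm H2O.
#' @param pes_gain_error Multiplicative esophageal-pressure calibration
#'   error (> 0); 1 is a perfectly calibrated balloon.
#' @param pes_baseline End-expiratory esophageal pressure, cm H2O.
#' @param sex `"male"` or `"female"`; used by the predicted chest-wall
#'   elastance formula.
#' @param height_cm Standing height, cm.
#'
#' @return A list of class `pocc_mechanics`.
#' @seealso [simulate_recording()], [predicted_chest_wall_elastance()]
#' @export
patient_mechanics <- function(lung_elastance = 15,
                              chest_wall_elastance = 5,
                              resistance = 10,
                              effort_amplitude_mean = 20,
                              effort_amplitude_sd_within = 1.5,
                              neural_insp_time = 0.9,
                              respiratory_rate = 22,
                              dynamic_attenuation = 0.74,
                              edi_gain = 1,
                              pes_gain_error = 1,
                              pes_baseline = 8,
                              sex = "male",
                              height_cm = 175) {
  check_number(lung_elastance, "lung_elastance", 0, allow_equal_lower = FALSE)
  check_number(chest_wall_elastance, "chest_wall_elastance", 0,
               allow_equal_lower = FALSE)
  check_number(resistance, "resistance", 0, allow_equal_lower = FALSE)
  check_number(effort_amplitude_mean, "effort_amplitude_mean", 0)
  check_number(effort_amplitude_sd_within, "effort_amplitude_sd_within", 0)
  check_number(neural_insp_time, "neural_insp_time", 0,
               allow_equal_lower = FALSE)
  check_number(respiratory_rate, "respiratory_rate", 0,
               allow_equal_lower = FALSE)
  check_number(dynamic_attenuation, "dynamic_attenuation", 0, 1,
               allow_equal_lower = FALSE)
  check_number(edi_gain, "edi_gain", 0)
  check_number(pes_gain_error, "pes_gain_error", 0, allow_equal_lower = FALSE)
  check_number(pes_baseline, "pes_baseline")
  sex <- match.arg(sex, c("male", "female"))
  check_number(height_cm, "height_cm", 100, 230)
  if (neural_insp_time >= 0.8 * 60 / respiratory_rate) {
    abort("`neural_insp_time` must be < 80% of the breath period.")
  }
  structure(
    list(
      lung_elastance = lung_elastance,
      chest_wall_elastance = chest_wall_elastance,
      resistance = resistance,
      effort_amplitude_mean = effort_amplitude_mean,
      effort_amplitude_sd_within = effort_amplitude_sd_within,
      neural_insp_time = neural_insp_time,
      respiratory_rate = respiratory_rate,
      dynamic_attenuation = dynamic_attenuation,
      edi_gain = edi_gain,
      pes_gain_error = pes_gain_error,
      pes_baseline = pes_baseline,
      sex = sex,
      height_cm = height_cm
    ),
    class = "pocc_mechanics"
  )
}

#' Ventilator settings for the simulator
#'
#' @param mode `"PSV"` (pressure support), `"PCV"` (pressure
#'   assist-control) or `"VCV"` (volume assist-control).
#' @param support_level Pressurization above PEEP, cm H2O (PSV/PCV).
#' @param peep Set positive end-expiratory pressure, cm H2O.
#' @param trigger_flow_threshold Patient-generated inspiratory flow that
#'   triggers the ventilator, L/s.
#' @param cycle_fraction Fraction of peak inspiratory flow at which PSV
#'   cycles off, in (0, 1).
#' @param rise_time Pressurization time constant, s.
#' @param set_insp_time Set inspiratory time, s (PCV).
#' @param set_tidal_volume Set tidal volume, L (VCV).
#' @param set_flow Set constant inspiratory flow, L/s (VCV).
#' @param backup_rate Time-triggered backup rate for assist-control modes,
#'   breaths/min; used when the patient generates no trigger (passive
#'   simulation under PCV/VCV).
#'
#' @return A list of class `pocc_vent`.
#' @export
vent_settings <- function(mode = c("PSV", "PCV", "VCV"),
                          support_level = 6,
                          peep = 8,
                          trigger_flow_threshold = 0.1,
                          cycle_fraction = 0.25,
                          rise_time = 0.15,
                          set_insp_time = 1,
                          set_tidal_volume = 0.45,
                          set_flow = 0.9,
                          backup_rate = 12) {
  mode <- match.arg(mode)
  check_number(support_level, "support_level", 0)
  check_number(peep, "peep", 0)
  check_number(trigger_flow_threshold, "trigger_flow_threshold", 0,
               allow_equal_lower = FALSE)
  check_number(cycle_fraction, "cycle_fraction", 0, 1,
               allow_equal_lower = FALSE, allow_equal_upper = FALSE)
  check_number(rise_time, "rise_time", 0, allow_equal_lower = FALSE)
  check_number(set_insp_time, "set_insp_time", 0, allow_equal_lower = FALSE)
  check_number(set_tidal_volume, "set_tidal_volume", 0,
               allow_equal_lower = FALSE)
  check_number(set_flow, "set_flow", 0, allow_equal_lower = FALSE)
  check_number(backup_rate, "backup_rate", 0, allow_equal_lower = FALSE)
  structure(
    list(
      mode = mode, support_level = support_level, peep = peep,
      trigger_flow_threshold = trigger_flow_threshold,
      cycle_fraction = cycle_fraction, rise_time = rise_time,
      set_insp_time = set_insp_time, set_tidal_volume = set_tidal_volume,
      set_flow = set_flow, backup_rate = backup_rate
    ),
    class = "pocc_vent"
  )
}

#' Simulation configuration
#'
#' Defaults emulate one daily bedside session: a 10-minute recording
#' sampled at 100 Hz with 15 randomly interleaved whole-breath
#' end-expiratory occlusions.
#'
#' @param sampling_rate Sampling rate, Hz (>= 50).
#' @param duration Recording duration, s.
#' @param n_occlusions Number of occlusion maneuvers scheduled on randomly
#'   chosen eligible breaths.
#' @param noise_sd Gaussian measurement noise SD added to Paw and Pes,
#'   cm H2O.
#' @param cardiac_artifact_amplitude Amplitude of the sinusoidal cardiac
#'   oscillation added to Pes, cm H2O.
#' @param cardiac_rate Cardiac rate, beats/min.
#' @param edi_noise_sd Gaussian noise SD added to the Edi channel, uV.
#' @param timing_jitter SD of the breath-to-breath fractional variation in
#'   breath period (dimensionless). Real breathing is not metronomic; the
#'   jitter also decoheres respiratory harmonics from the cardiac tone.
#' @param peak_fraction Fraction of the neural inspiratory time at which the
#'   raised-cosine effort profile peaks.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#'
#' @return A list of class `pocc_simconfig`.
#' @export
sim_config <- function(sampling_rate = 100,
                       duration = 600,
                       n_occlusions = 15,
                       noise_sd = 0.2,
                       cardiac_artifact_amplitude = 1,
                       cardiac_rate = 80,
                       edi_noise_sd = 0,
                       timing_jitter = 0.05,
                       peak_fraction = 0.5,
                       seed = NULL) {
  check_number(sampling_rate, "sampling_rate", 50)
  check_number(duration, "duration", 1)
  check_count(n_occlusions, "n_occlusions", 0)
  check_number(noise_sd, "noise_sd", 0)
  check_number(cardiac_artifact_amplitude, "cardiac_artifact_amplitude", 0)
  check_number(cardiac_rate, "cardiac_rate", 0, allow_equal_lower = FALSE)
  check_number(edi_noise_sd, "edi_noise_sd", 0)
  check_number(timing_jitter, "timing_jitter", 0, 0.2)
  check_number(peak_fraction, "peak_fraction", 0.1, 0.9)
  if (!is.null(seed)) check_count(seed, "seed")
  structure(
    list(
      sampling_rate = sampling_rate, duration = duration,
      n_occlusions = as.integer(n_occlusions), noise_sd = noise_sd,
      cardiac_artifact_amplitude = cardiac_artifact_amplitude,
      cardiac_rate = cardiac_rate, edi_noise_sd = edi_noise_sd,
      timing_jitter = timing_jitter, peak_fraction = peak_fraction,
      seed = seed
    ),
    class = "pocc_simconfig"
  )
}
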