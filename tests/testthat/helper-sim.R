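# Shared fixtures, generated in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default-conditions recording: noise and cardiac artifact on.
default_rec <- function() {
  cached_fixture("default_rec", simulate_recording(
    patient_mechanics(), vent_settings(),
    sim_config(duration = 150, n_occlusions = 6, seed = 7)
  ))
}

# Clean recording: no noise, no cardiac artifact, perfect Pes calibration.
clean_rec <- function() {
  cached_fixture("clean_rec", simulate_recording(
    patient_mechanics(effort_amplitude_mean = 12,
                      effort_amplitude_sd_within = 0),
    vent_settings(),
    sim_config(duration = 90, n_occlusions = 4, noise_sd = 0,
               cardiac_artifact_amplitude = 0, seed = 2)
  ))
}

default_analysis <- function() {
  cached_fixture("default_analysis",
                 suppressMessages(analyze_recording(default_rec())))
}

clean_analysis <- function() {
  cached_fixture("clean_analysis", suppressMessages(
    analyze_recording(clean_rec(), remove_cardiac = FALSE)
  ))
}

# Small cohort under default (noisy) conditions, shortened recordings.
small_cohort <- function() {
  cached_fixture("small_cohort", simulate_cohort(
    8, 2, config = sim_config(duration = 90, n_occlusions = 4), seed = 31
  ))
}

small_cohort_summaries <- function() {
  cached_fixture("small_cohort_summaries",
                 suppressMessages(analyze_cohort(small_cohort())))
}
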