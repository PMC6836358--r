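# End-to-end reproducible workflow: simulate -> segment -> analyze ->
# predict -> validate, with a YAML-serializable configuration whose
# defaults are the method's published constants.

#' Pipeline configuration
#'
#' All defaults equal the method's standard values: esophageal-validity
#' band 0.7-1.3, screening thresholds 10/15 cm H2O (Pmus) and 15/20 cm H2O
#' (delta-PL,dyn), conversion factors k1 = -3/4 and k2 = 2/3, three
#' occlusions per prediction, 100 cross-validation repetitions. Every field
#' can be overridden, and a config round-trips through YAML.
#'
#' @param seed Global seed fanned out deterministically to every stage.
#' @param n_patients,recordings_per_patient Cohort size for simulation.
#' @param sampling_rate,duration,n_occlusions Simulator settings (see
#'   [sim_config()]).
#' @param validity_band Inclusive band for the occlusion/esophageal ratio.
#' @param pmus_thresholds,pl_thresholds Screening thresholds, cm H2O.
#' @param k1,k2 Conversion factors used for screening.
#' @param n_occ_prediction Occlusions per prediction.
#' @param cv_reps Cross-validation repetitions.
#' @return A list of class `pocc_config`.
#' @export
run_config <- function(seed = 1L, n_patients = 16,
                       recordings_per_patient = 3,
                       sampling_rate = 100, duration = 600,
                       n_occlusions = 15,
                       validity_band = c(0.7, 1.3),
                       pmus_thresholds = c(10, 15),
                       pl_thresholds = c(15, 20),
                       k1 = -3 / 4, k2 = 2 / 3,
                       n_occ_prediction = 3, cv_reps = 100) {
  cfg <- as.list(environment())
  structure(cfg, class = "pocc_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return `read_run_config()` returns a `pocc_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A [run_config()] object.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Run the full pipeline and write its artifacts
#'
#' Simulates a cohort, writes every recording (waveform CSV + metadata
#' YAML), analyzes all recordings, screens the valid ones, cross-validates
#' the method, and writes `summaries.csv`, `predictions.csv`, `truth.csv`
#' and `report.json` under `out_dir`. Every artifact set is stamped with
#' the configuration hash and seed in `run_info.json`, and each stage logs
#' its counts.
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param write_waveforms Write the per-recording waveform CSVs (large);
#'   summaries and reports are always written.
#' @return Invisibly, a list with the in-memory artifacts (`cohort`,
#'   `summaries`, `predictions`, `factors`, `crossval`).
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         write_waveforms = FALSE) {
  stopifnot(inherits(config, "pocc_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  cohort <- stage("simulate", simulate_cohort(
    n_patients = config$n_patients,
    recordings_per_patient = config$recordings_per_patient,
    config = sim_config(sampling_rate = config$sampling_rate,
                        duration = config$duration,
                        n_occlusions = config$n_occlusions),
    seed = config$seed
  ))
  inform(sprintf("simulated %d recordings in %d patients",
                 length(cohort$recordings), config$n_patients))
  if (write_waveforms) {
    wf_dir <- file.path(out_dir, "waveforms")
    dir.create(wf_dir, showWarnings = FALSE)
    for (key in names(cohort$recordings)) {
      write_recording(cohort$recordings[[key]],
                      file.path(wf_dir, paste0(key, ".csv")))
    }
  }

  summaries <- stage("analyze", analyze_cohort(
    cohort, validity_band = config$validity_band
  ))
  n_excl <- sum(!summaries$valid)
  inform(sprintf(
    "analyzed %d recordings: %d breaths, %d occlusions, %d excluded by the validity filter",
    nrow(summaries), sum(summaries$n_breaths),
    sum(summaries$n_occlusions), n_excl
  ))

  factors <- conversion_factors(k1 = config$k1, k2 = config$k2)
  predictions <- stage("predict", screen_cohort(
    summaries, factors = factors,
    pmus_thresholds = config$pmus_thresholds,
    pl_thresholds = config$pl_thresholds,
    n_occ = config$n_occ_prediction,
    seed = child_seed(config$seed, 101L)
  ))
  inform(sprintf("screened %d valid recordings", nrow(predictions)))

  crossval <- stage("validate", cross_validate(
    summaries,
    reps = config$cv_reps,
    n_occ = config$n_occ_prediction,
    pmus_thresholds = config$pmus_thresholds,
    pl_thresholds = config$pl_thresholds,
    seed = child_seed(config$seed, 211L)
  ))

  flat <- function(df) {
    df <- as_tibble(df)
    df[vapply(df, is.list, logical(1))] <- NULL
    df
  }
  readr::write_csv(flat(summaries), file.path(out_dir, "summaries.csv"))
  readr::write_csv(flat(predictions), file.path(out_dir, "predictions.csv"))
  readr::write_csv(cohort$truth, file.path(out_dir, "truth.csv"))
  jsonlite::write_json(
    list(crossval_summary = glance(crossval),
         crossval_results = tidy(crossval)),
    file.path(out_dir, "report.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(seed = config$seed, config_hash = rlang::hash(unclass(config)),
         config = unclass(config)),
    file.path(out_dir, "run_info.json"), auto_unbox = TRUE
  )

  invisible(list(cohort = cohort, summaries = summaries,
                 predictions = predictions, factors = factors,
                 crossval = crossval))
}
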