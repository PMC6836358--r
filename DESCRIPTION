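Package: poccscreen
Title: Non-Invasive Screening of Inspiratory Effort from Expiratory
    Occlusion Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting excessive inspiratory muscle pressure (Pmus)
    and dynamic transpulmonary driving pressure during assisted mechanical
    ventilation from the airway-pressure deflection generated during a
    whole-breath end-expiratory occlusion (the occlusion pressure, delta-Pocc).
    Includes a physiologically structured single-compartment waveform
    simulator with patient effort and randomly interleaved one-way
    occlusions, breath segmentation and occlusion detection for
    multi-channel ventilator recordings, per-breath reference metrics from
    esophageal manometry (delta-Pes, delta-PL,dyn, Pmus, PTPmus), the
    conversion-factor prediction equations with threshold screening, and the
    derivation/validation statistics: mixed-effects conversion-factor
    estimation, repeated-measures Bland-Altman agreement, ROC screening
    accuracy, and repeated cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
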