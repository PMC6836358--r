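# poccscreen

Non-invasive screening for excessive inspiratory effort and dynamic lung
stress during assisted mechanical ventilation, from the airway-pressure
deflection during a whole-breath end-expiratory occlusion.

## The problem

Spontaneously breathing ICU patients on assisted ventilation can generate
injuriously large inspiratory efforts. Excessive respiratory muscle
pressure (Pmus) risks load-induced diaphragm injury, and the resulting
swings in pleural pressure drive the dynamic transpulmonary driving
pressure (ΔP<sub>L,dyn</sub>) — the stress actually applied to the lung —
well above what the airway pressure on the ventilator display suggests.
Measuring these quantities directly requires an esophageal balloon
catheter, which is invasive and rarely available at the bedside.

A brief end-expiratory occlusion offers a shortcut. Against a closed
airway no gas flows, so the patient's effort is inscribed directly on
airway pressure: the maximal deflection below PEEP during the occluded
breath (ΔP<sub>occ</sub>, negative by convention) is a quasi-static
measure of the effort that drives the esophageal-pressure swing on
flowing breaths. Because muscle force falls when the muscle is allowed to
shorten (the force–velocity relation), the dynamic swing is a roughly
constant fraction of the quasi-static one, and two conversion factors
turn three occlusion maneuvers into a screening test:

```
Pmus_predicted     = k1 × mean(ΔPocc)                 k1 < 0
ΔPL,dyn_predicted  = ΔPaw,dyn − k2 × mean(ΔPocc)      k2 > 0
```

with default factors k1 = −3/4 and k2 = 2/3 and screening thresholds of
10/15 cm H2O for Pmus and 15/20 cm H2O for ΔP<sub>L,dyn</sub>. Recordings
in which the ratio ΔP<sub>occ</sub>/ΔP<sub>es</sub> falls outside 0.7–1.3
indicate an unreliable esophageal signal and are excluded before any
derivation or prediction.

`poccscreen` implements the full method in tidy R: a physiologically
structured waveform simulator (single-compartment mechanics, patient
effort, one-way occlusions, esophageal miscalibration, cardiac artifact),
breath segmentation and occlusion detection, the per-breath reference
metrics (ΔP<sub>es</sub>, ΔP<sub>L,dyn</sub>, Pmus, PTP<sub>mus</sub>),
the prediction equations with threshold screening, and the validation
statistics: mixed-model conversion-factor derivation, repeated-measures
Bland–Altman agreement, ROC discrimination, and repeated patient-level
cross-validation. Everything is exercised end to end on simulated
cohorts, so the whole pipeline is testable without patient data.

## Worked example

Simulate one 10-minute bedside session (15 random occlusions), analyze
it, and screen it:

```r
library(poccscreen)

rec <- simulate_recording(
  patient_mechanics(effort_amplitude_mean = 22),
  vent_settings(),
  sim_config(duration = 600, n_occlusions = 15, seed = 42)
)
an <- analyze_recording(rec)
an$summary
#>   patient   day n_breaths n_occlusions mean_pmus mean_delta_pes mean_delta_paw
#> 1 P1          1       204           15      16.5          -14.6           6.16
#>   mean_delta_pl_dyn mean_ptp_mus mean_delta_pocc pocc_pes_ratio valid
#> 1              20.0         6.56           -22.1           1.01 TRUE

screen_recording(an$summary, n_occ = 3, seed = 1)
#>   patient   day pmus_pred delta_pl_pred pocc_used pmus_gt10 pmus_gt15 pl_gt15 pl_gt20
#> 1 P1          1      16.9          21.2 <dbl [3]> TRUE      TRUE      TRUE    TRUE
```

The recording is usable (occlusion/esophageal ratio 1.01, inside
0.7–1.3). From three randomly chosen occlusions the method predicts a
mean Pmus of 16.9 cm H2O and a ΔP<sub>L,dyn</sub> of 21.2 cm H2O —
both flagged as excessive at every threshold, and close to the measured
reference values (16.5 and 20.0 cm H2O) that an esophageal catheter
would have provided. The occlusion itself does not perturb respiratory
drive: peak Edi agrees between occluded and non-occluded breaths
(`edi_drive_check(an$metrics)`: mean difference −0.003 µV, limits of
agreement ±4.1 µV).

Cohort-level work follows the same verbs:

```r
cohort    <- simulate_cohort(16, 3, seed = 1)     # 16 patients × 3 days
summaries <- analyze_cohort(cohort)
factors   <- derive_conversion_factors(summaries) # k1, k2 with 95% CIs
cv        <- cross_validate(summaries, truth = cohort$truth, reps = 100)
glance(cv)                                        # median AUROCs, agreement
autoplot(cv)
```

A thin command-line front end (`inst/cli/pocc`) exposes the same stages
as `simulate`, `segment`, `analyze`, `predict`, `validate` and `run-all`
subcommands for shell pipelines.

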