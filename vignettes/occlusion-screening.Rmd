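---
title: "Occlusion-pressure screening: model, simulator and validation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occlusion-pressure screening: model, simulator and validation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poccscreen)
```

This vignette is the package's account of the science it implements: the
physiological model behind occlusion-pressure screening, how the built-in
simulator emulates bedside recordings, the signal-processing and
statistical choices, and what the passing test suite does and does not
demonstrate about real patient data.

## The physiological model

During assisted ventilation the pressure inflating the respiratory system
is shared between the ventilator and the patient's inspiratory muscles.
For a linear single-compartment system,

$$P_{aw}(t) + P_{mus}(t) = \mathrm{PEEP} + E_{rs}\,V(t) + R\,\dot V(t),$$

with $E_{rs} = E_L + E_{cw}$ the respiratory-system elastance (lung plus
chest wall) and $R$ the resistance. Esophageal pressure ($P_{es}$) tracks
pleural pressure: during a breath it rises with chest-wall recoil
($E_{cw} V$) and falls with muscle contraction, so the muscle pressure on
any breath can be reconstructed as
$P_{mus}(t) = E_{cw} V(t) - (P_{es}(t) - P_{es,\mathrm{onset}})$, which
is zero at onset by construction. Its inspiratory peak is the per-breath
effort, and its inspiratory time-integral (clipped at zero) is the
pressure–time product PTP~mus~, the reference standard for effort. The
dynamic transpulmonary driving pressure is the inspiratory rise of
$P_L = P_{aw} - P_{es}$ from effort onset to peak.

Against an occluded airway no gas flows, volume is constant, and the
resistive and elastic terms vanish: the full quasi-static effort is
inscribed on airway pressure as a deflection below PEEP, $\Delta P_{occ}$.
On flowing breaths the same neural drive produces a *smaller* pressure
swing because shortening muscle generates less force (the force–velocity
relation) — the ratio of dynamic to quasi-static swing is the
*dynamic attenuation*. That near-constant attenuation is what makes the
two conversion factors work:

$$P_{mus,pred} = k_1 \,\overline{\Delta P_{occ}}, \qquad
  \Delta P_{L,dyn,pred} = \Delta P_{aw,dyn} - k_2\, \overline{\Delta P_{occ}}.$$

$|k_1|$ estimates the attenuation itself; $k_2$ is smaller than $|k_1|$
by roughly $E_{cw} V_t / A$ (the chest-wall recoil reclaims part of the
esophageal swing), which is why the method's canonical values are
$k_1 = -3/4$ and $k_2 = 2/3$. Prediction is only defined when
$\Delta P_{occ} < 0$: without inspiratory effort the esophageal swing is
positive and carries no information about lung stress.

## What the simulator emulates

`simulate_recording()` integrates the equation of motion with a
fixed-step explicit scheme at the sampling rate (default 100 Hz). The
linear single-compartment model is stiff-free, so a first-order scheme at
100 Hz keeps amplitude errors well below the 1% granularity asserted by
the quasi-static identity checks while remaining exactly reproducible.

* **Effort profile.** Each breath's muscle pressure is a raised cosine
  over the neural inspiratory time (default 0.9 s), peaking at half the
  inspiratory time; the per-breath amplitude is drawn from a truncated
  normal (defaults 20 ± 1.5 cm H2O within a recording). The profile shape
  is a modeling choice — any smooth rise–fall works; the raised cosine
  integrates to half the neural time exactly, which gives a closed-form
  ground-truth PTP.
* **Ventilator.** PSV (flow-triggered at 0.1 L/s of patient-generated
  flow, pressurization time constant 0.15 s, cycling at 25% of peak
  inspiratory flow), PCV (time-cycled) and VCV (constant flow) with a
  backup rate for passive patients. Defaults (support 6 cm H2O above
  PEEP 8) put the airway driving pressure near 6 cm H2O, matching the
  low-support conditions under which the screening method matters most.
* **Occlusions.** A scheduled breath's one-way valve clamps inspiratory
  flow to zero, holds volume at the end-expiratory level for the duration
  of the single effort, and writes $P_{aw} = \mathrm{PEEP} -
  \mathrm{effort}(t)$. Expiratory relief below baseline is not simulated:
  at end-expiration there is no gas above FRC to exhale.
* **Dynamic attenuation** (default 0.74) scales the applied muscle
  pressure on flowing breaths only. Edi follows the *unattenuated*
  profile with a per-patient gain, so occluded and non-occluded breaths
  carry identical neural drive — the property the Edi invariance check
  verifies.
* **Esophageal signal.** $P_{es} = \mathrm{baseline} + E_{cw}V -
  \mathrm{effort}$, multiplied by a calibration gain error (1 = perfect
  balloon), plus a sinusoidal cardiac oscillation (default 1 cm H2O at
  80/min) and Gaussian noise (default 0.2 cm H2O, also added to Paw).
* **Timing jitter.** Breath periods vary by 5% (SD) breath to breath.
  Real breathing is not metronomic, and the jitter also decoheres the
  respiratory harmonics that would otherwise masquerade as a cardiac
  tone.

`simulate_cohort()` draws patient-level parameters once per patient
(between-patient SDs: effort 8 cm H2O, attenuation 0.06, elastance
4 cm H2O/L, and a log-normal esophageal gain error with SD 0.12) and
day-level deviations per recording. Each patient consumes a deterministic
child seed, so extending a cohort never perturbs existing patients. The
default effort distribution deliberately spans the 10 and 15 cm H2O
screening thresholds, because a screening test can only be validated on a
cohort in which both classes occur.

### What it does not emulate

Pendelluft and two-compartment mechanics, intrinsic PEEP, expiratory
muscle activity, NAVA, leaks, secretions, swallowing and esophageal
spasm artifacts, and non-sinusoidal (real) cardiac artifacts are all out
of scope. Passing tests therefore demonstrate internal consistency of the
method under the stated physiological idealization — not performance on
real recordings, whose artifact structure is richer.

## Signal conditioning and per-breath analysis

Breaths are segmented from flow: an upward crossing of 0.02 L/s sustained
for 100 ms starts a breath (hysteresis rejects noise crossings),
inspiration ends when flow returns to zero, and the breath ends at the
next start. Spans are 1-based and half-open; partial breaths at the
recording edges — including any breath starting within 0.5 s of an edge,
where zero-phase filter transients live — are discarded. Occluded breaths
carry no flow and are instead delimited by the airway-pressure deflection
episode: low-passed Paw more than 1 cm H2O below set PEEP with |flow| <
0.02 L/s throughout, expanded to a 0.3 cm H2O hysteresis level. Set PEEP
comes from metadata, not from measured end-expiratory pressure, because
the maneuver's deflection is referenced to the set level. Both detection
thresholds are package choices; the method's description specifies
neither.

Extrema and integrals are taken from conditioned channels: a zero-phase
4th-order Butterworth low-pass at 5 Hz, plus subtraction of the dominant
cardiac tone from Pes. The cardiac oscillation (≈1.3 Hz) lies *inside*
the effort band, so no effort-preserving low-pass can remove it; instead
the tone is located as the periodogram peak in 0.75–3 Hz — after masking
neighborhoods of the respiratory harmonics (fundamental found below
0.7 Hz; mask half-widths grow with harmonic number because timing jitter
broadens higher harmonics) — refined by sinusoid regression, and
subtracted only if its fit is coherent across the two halves of the
recording (amplitude > 0.25 cm H2O in both, phase agreement < 0.8 rad).
A stationary cardiac tone passes this guard; a decohering respiratory
harmonic does not. Quasi-static (occluded-breath) swings are measured on
the low-pass-only channel: they are large relative to the artifact, and
an imperfect tone fit would bias them more than the artifact itself.
Raw channels are never overwritten.

The effort onset — the baseline for $\Delta P_{es}$, $P_{mus}$ and
$\Delta P_{L,dyn}$ — is the last pre-inspiratory local maximum of
conditioned Pes within 300 ms before flow onset, capturing effort that
begins before the ventilator triggers; the description of the method
says only "from onset to peak". Tidal volume integrates drift-corrected
flow (a constant offset removed so volume returns to baseline at breath
end). PTP~mus~ integrates clipped $P_{mus}$ over the flow-defined
inspiration, the windowing the method itself uses.

The esophageal-validity ratio is computed *within* occluded breaths
(mean of $\Delta P_{occ}/\Delta P_{es}$ per occlusion): under the
quasi-static identity the two swings are equal, so the ratio directly
estimates the inverse calibration gain. Whether the original description
intends the denominator from occluded or flowing breaths is ambiguous;
the within-occlusion reading is the physically grounded one and is the
package's documented choice. The 0.7–1.3 band is inclusive at both ends,
since exclusion is stated strictly ("greater than 1.3 or less than
0.7").

## Statistical methods

* **Conversion factors.** Per-recording ratios (mean Pmus or mean
  $\Delta P_{es}$ over mean $\Delta P_{occ}$) are modeled with a
  patient-level random intercept (REML); the fixed intercept is the
  factor, with a Wald 95% CI. Degenerate inputs (zero variance, fewer
  than three patients, non-convergence) fall back to averaging patient
  means — which reproduces constant-ratio cohorts exactly.
* **Repeated-measures Bland–Altman.** Differences of log values are
  decomposed into fixed bias, between-patient SD and within-patient
  residual SD. The within-patient limits are reported as a percentage of
  the estimate, `la_pct_within = 100 × 1.96 × SD_within,log` — the
  small-sigma proportional reading of log-scale limits, chosen so the
  statistic matches its closed form under multiplicative noise. A
  parallel raw-scale decomposition supplies the between-patient SD in
  cm H2O, and total limits follow
  `1.96 × SD_bias,btw + LA%,within × estimate`.
* **Discrimination.** The AUROC is the empirical rank statistic
  (midranks, i.e. concordant pairs plus half-ties), with a seeded
  patient-level bootstrap percentile CI (2000 resamples); sensitivity and
  specificity use the same strict-inequality positivity call as the
  screening flags.
* **Cross-validation.** Each of 100 repetitions splits *patients* in
  half (odd counts round toward derivation), derives factors on one half
  and evaluates prediction, agreement and discrimination on the other;
  derivation and validation patient sets are asserted disjoint in every
  repetition. The three occlusions per prediction are an unweighted
  random sample without replacement; their arithmetic mean enters the
  equations (for affine maps, averaging before or after prediction is
  identical, so no second aggregation rule is offered). Repetitions with
  a one-class validation half report that metric as undefined and are
  excluded from summaries, with the count reported.

## Numerical choices and degenerate inputs

Integration is fixed-step explicit Euler at the sampling rate;
reproducibility is valued over order for this stiff-free system. Volume
"conservation" holds in the cyclic-stationary sense: with realistic
expiratory time constants a few mL of the tidal volume remain at the next
onset, but the end-expiratory level itself is stationary within 1 mL
under constant effort, which is what the conservation test asserts.
Mixed-model convergence uses lme4 defaults with singular fits tolerated
and a moment fallback. Screening comparisons are strict (`>`), matching
"exceeded". All randomness flows from explicit integer seeds through
deterministic child seeds (kept below $2^{31}$).

The chest-wall elastance predictor is a deliberate placeholder contract:
a constant divided by predicted vital capacity (simplified adult
spirometric reference at fixed mid-age), calibrated so a 175 cm male
yields 5 cm H2O/L, monotone decreasing in predicted capacity, and fully
overridable with a measured value — the original supplementary formula is
not reproduced in the main description of the method.

## Problem sizes in the test suite

The suite exercises full 10-minute recordings where the study conditions
demand them (the default cohort for discrimination) and shorter 45–180 s
recordings with proportionally fewer occlusions for the repeated
property checks (filter sweeps over 50 seeds, 20-cohort estimator-bias
loops), a package choice balancing statistical resolution against suite
runtime. The simulator's physiological defaults are never altered for
those checks — only duration and occlusion count scale.

## Known limitations

The validity of the conversion factors rests on the attenuation being
stable within patient and day; the simulator draws it that way by
construction, so cross-validated discrimination here is an upper bound on
bedside performance. The cardiac-tone subtraction assumes a
near-stationary heart rate over the recording; rate drifts would leave
residual artifact (bounded by the artifact amplitude itself). Predicted
chest-wall elastance is an empirical stand-in whose error propagates
directly into Pmus and PTP~mus~; the reference-metric tests quantify the
pipeline's accuracy with the *true* elastance supplied.
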