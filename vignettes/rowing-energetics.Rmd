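---
title: "The energy cost of ergometer rowing: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The energy cost of ergometer rowing: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rowergetics)
```

## The statistic

Locomotor performance can be compressed into a ratio: the speed a rower can
sustain is the metabolic power available (J s^-1^) divided by the energy cost
of covering one metre (J m^-1^). The numerator — maximal oxygen uptake, power
at VO2max, lactate thresholds — is measured routinely in elite rowing. This
package computes the denominator for the air-braked rowing ergometer: the
**energy cost of rowing (ECR)**, in oxygen-equivalent millilitres per metre,

$$\mathrm{ECR} \;=\; \frac{\dot{V}O_2 \;+\;
  \frac{d[La^-]_b}{dt}\times 3.3 \times \mathrm{mass}}
  {\text{mean step speed}}$$

with oxygen uptake in mL min^-1^, speed in m min^-1^, and the blood-lactate
accumulation rate (mmol L^-1^ min^-1^) converted into oxygen units with the
conventional equivalent of 3.3 mLO~2~ kg^-1^ per mmol L^-1^. The lactate term
credits the non-oxidative glycolytic pathway, which contributes a growing
share of energy as intensity rises; lactate that is produced and then
oxidised is already counted in the measured VO~2~, so the term operates on
*net* blood accumulation only. Dividing by body mass gives ECR in
mLO~2~ kg^-1^ m^-1^, the unit used throughout (heavyweight rowers differ in
mass by 20 kg or more, and mass itself correlates with performance).

On the ergometer, speed is virtual: the monitor converts power to pace
through the cube-law drag model `pace = (k / P)^(1/3)` with `k = 2.8` W at
1 m s^-1^ for the standard calibration. The implementation treats `k` as a
configuration constant (`drag_constant`). At 400 W this relation gives
5.23 m s^-1^, the speed at which the cohort-level ECR plateau sits.

## Pipeline assumptions and tunable parameters

Each subject contributes an incremental test (steps of 3 min work at
200 W + 50 W increments with a ~27 s sampling rest, gas exchange, end-of-step
earlobe lactate) and a 2,000 m all-out performance. The analysis makes the
following choices, all exposed in `analysis_config()`:

* **Time base of the lactate rate** (`include_rest_in_dt`, default `FALSE`):
  the accumulation rate divides by the 3 min of rowing, not rowing + rest —
  the rate in the ECR numerator is a *work* rate. The source protocol does
  not state which convention was used, so it is a switch.
* **First-step baseline** (`baseline_lactate`, 1.0 mmol L^-1^): resting
  lactate is rarely sampled in routine testing; 1.0 is a standard resting
  value for fasted athletes at rest.
* **Clearance floor** (`lactate_floor`, `TRUE`): a *negative* lactate change
  means net clearance, which is oxidative disposal already captured by
  VO~2~; letting it subtract from the numerator would undercount the aerobic
  cost. The raw (unfloored) rate is still reported per step.
* **Lactate-curve degree** (`polynomial_degree`, 3): the thresholds at 2 and
  4 mmol L^-1^ come from a least-squares polynomial of lactate against
  power, solved on *rising* segments only (a wiggly cubic can cross a target
  twice; the physiologically meaningful crossing is the lowest rising one).
  Degree 3 is the common field choice and robust to assay noise on 5–7
  points. On curves of exponential shape a cubic carries a small systematic
  overshoot of the crossing power (several watts over a 6-step test); the
  parameter-recovery tests therefore use degree 4, for which the bias on
  noise-free data is below half a watt over the protocol range.
* **VO2 and HR at threshold**: evaluated from *linear* fits against power
  over submaximal steps (both are linear below VO2max), never from the
  lactate polynomial.
* **VO2max criteria** (`vo2max_criteria()`): VO2max is the highest per-step
  VO2; WVO2max the lowest power within `plateau_tolerance` (150 mL min^-1^)
  of it; attainment flags (VO2 plateau, RER ≥ 1.10, HR vs age-predicted
  maximum, end lactate ≥ 8 mmol L^-1^) are reported but never enforced —
  the pipeline must not drop an athlete silently.
* **Plateau detection** (`plateau_slope_max`, 0.25; `pooling_min_n`, 3): the
  ECR-vs-speed plateau onset is estimated by a continuous two-segment least
  squares fit with the breakpoint restricted to observed step speeds — the
  steps are the sampling resolution, so a finer-grained breakpoint would be
  an artefact of the fit, not of the data. The candidate with minimal
  residual sum of squares wins; exact ties resolve to the highest speed. A
  plateau is declared when the upper slope falls below a quarter of the
  lower one. Pooled per-step cohort means enter the fit only when at least
  `pooling_min_n` subjects completed the step: a "cohort mean" computed
  over the one or two strongest finishers of the top step is dominated by
  selection, not by the speed effect.
* **Mixed model**: the speed effect on ECR is tested with a random-intercept
  model (subject as the random effect) fitted by REML through `nlme` —
  speed enters as a *categorical* step factor, matching the per-step
  post-hoc contrasts; all pairwise contrasts are Wald t-tests on the fixed
  effects, adjusted together by Benjamini–Hochberg FDR. Correlation tables
  report raw p and FDR-adjusted q side by side.

## Indirect calorimetry

When only mixed-expired fractions and spirometer volumes are available, gas
exchange uses the standard open-circuit computation: ATPS volumes are
standardised to STPD with the Magnus saturation-vapour-pressure formula,
inspired ventilation follows from nitrogen conservation (Haldane transform),
and VO~2~/VCO~2~ from the fraction differences. Volumes already standardised
can be declared as such (`volume_convention = "stpd"`). Precomputed
VO~2~/VCO~2~ columns bypass this stage entirely.

Substrate partitioning uses the stoichiometric equations

$$\mathrm{Fat}\ (kcal\ min^{-1}) = (1.695\,\dot{V}O_2 - 1.701\,\dot{V}CO_2)
  \times 9.75$$
$$\mathrm{CHO}\ (kcal\ min^{-1}) = (4.585\,\dot{V}CO_2 - 3.226\,\dot{V}O_2)
  \times 4.07$$

with protein oxidation taken as negligible. The raw rates cross zero at
RER = 1.695/1.701 ≈ 0.996 (fat) and RER = 3.226/4.585 ≈ 0.704 (CHO) and go
negative outside that window — near exhaustion, bicarbonate buffering adds
non-metabolic CO~2~ and pushes RER past 1. Raw rates are preserved for
transparency; the fat *fraction* of energy supply is computed on rates
clipped at zero with an explicit `clipped` flag, since a percentage of a
negative rate has no physiological meaning.

## The synthetic cohort generator

No athlete data ship with the package. Instead `simulate_study()` draws
mechanistic virtual cohorts whose defaults emulate a squad of 21 heavyweight
international-level oarsmen: mass 88.3 ± 5.9 kg, height 1.91 ± 0.05 m, age
25.3 ± 3.7 y, VO2max 5.67 ± 0.36 L min^-1^, 2,000 m time around 6:00. Two
latent factors shape the correlation structure:

* a **size/fitness factor** loading on mass, height and VO2max, which
  (together with an anaerobic store proportional to mass) induces the
  mass–performance and VO2max–performance correlations seen in elite
  rowing;
* an **oxidative-phenotype factor** that simultaneously lowers the
  VO2-vs-power slope (better economy), delays the lactate onset power, and
  lowers the RER curve (more fat use). This encodes, as *correlation*, the
  observation that economical rowers also show higher fat oxidation and
  less lactate accumulation — the generator asserts no causal direction.

Within a test, aerobic demand is linear in power
(`vo2_rest + vo2_slope * W`, defaults 500 mL min^-1^ and
12.5 mL min^-1^ W^-1^) and caps at VO2max. True (muscle-side) lactate
follows `baseline + exp((W - onset)/shape)` with onset 328 W and shape
55.5 W — chosen because it inverts in closed form, giving exact 2 and
4 mmol L^-1^ crossings at 328 W and 328 + 55.5·ln 3 ≈ 389 W that the
threshold module must recover on noise-free subjects. The test terminates
when the next step would exceed the subject's lactate tolerance or run more
than one step past the VO2 cap.

**The measured-ECR plateau is a consequence, not an assertion.** Two
mechanisms produce it, both toggleable:

1. the VO2 cap — above it the aerobic numerator stops growing while speed
   keeps rising;
2. muscle-to-blood lactate transport inertia — earlobe lactate is the true
   value minus `lactate_lag_fraction` (0.45) of the part of the current
   step's increment exceeding `lactate_lag_onset` (0.5 mmol L^-1^), with
   `lactate_lag_carry` (0.6) of the previous deficit still outstanding one
   step later. Blood tracks slow accumulation closely (so the thresholds
   are barely displaced) but under-reports the surging increments of the
   final steps, flattening measured ECR exactly where the plateau is
   observed. With the lag off and the cap out of reach, measured ECR rises
   strictly to the end and the breakpoint fit declares no plateau — the
   mechanism-switch test.

The 2,000 m performance implements the power-to-cost ratio as a fixed
point: race speed solves `v = E(v) / C(v)` with available power
`E = 0.98 · VO2max + anaerobic_capacity / race duration` (store: 65 mLO~2~
equivalents per kg) and `C(v)` the subject's aerobic demand line
extrapolated to race power, per metre. The iteration uses the cube-root
rearrangement of `v·C(v) = E(v)`, which is strongly contractive because the
drag term is cubic in speed; the ratio form itself has a steep negative
slope near the root and oscillates.

All population spreads are truncated at ±3 SD (no 60 kg or 120 kg
"heavyweights"); measurement noise is added at the instrument level (VO2
75, VCO2 90 mL min^-1^; lactate assay 0.2 mmol L^-1^; HR 2 bpm). Identical
seed and configuration give byte-identical cohorts.

**What the generator does *not* emulate** — and therefore what passing
tests cannot certify about real data: breath-by-breath VO2 kinetics and
drift within a step, stroke-rate mechanics and their effect on efficiency,
pacing strategy within the 2,000 m, day-to-day biological variability,
lightweight or female cohorts, and the true (unpublished) within-subject
lactate kinetics of elite rowers, for which the exponential model is a
stated convenience. Cohort-level agreement with the calibration targets
shows the pipeline recovers the structure the generator encodes; it is not
evidence about any real squad.

## Numerical choices and degenerate inputs

* Threshold root-finding: bracketed `uniroot` at 10^-6^ W on a 4,001-point
  scan grid over the fitted power range extended by one step width;
  crossings beyond the observed range are flagged `extrapolated`. Multiple
  rising crossings pick the lowest power with a warning; no rising crossing
  raises "target never reached", which the pipeline serialises as an empty
  field, never a sentinel number.
* Broken-stick ties: RSS ties are resolved at a tolerance of 10^-9^ of the
  total sum of squares (scaled to the data, so a perfect straight line —
  where every candidate ties at zero RSS — resolves deterministically to
  the largest interior speed).
* Polynomial conditioning: lactate fits centre and scale power before
  fitting raw-coefficient polynomials.
* Subjects must complete at least two steps; incomplete final steps are not
  emitted by the generator and files containing single-step subjects drop
  them with a named warning.
* A single-subject "cohort" falls back from the mixed model to OLS with an
  explicit warning.

## Problem sizes

The shipped tests run cohorts of n = 21 (the emulated squad size), a
100-seed loop for the correlation sign-pattern property, a 25-seed loop for
calibration bands, and 1,000-subject draws for distributional checks; the
acceptance script averages its two stochastic quantities over 20 replicate
cohorts. These sizes keep the full suite under half a minute on one core
while leaving the Monte-Carlo standard errors well inside the tolerances
they are checked against.

## Known limitations

* ECR ignores the alactic (phosphocreatine) store and O2-deficit methods;
  over 3 min steps the alactic contribution is small but not zero.
* The lactate oxygen equivalent (3.3 mLO~2~ kg^-1^ mmol^-1^ L) is a
  population constant applied to all subjects.
* Threshold interpolation inherits the bias of polynomial fits on
  exponential-shaped curves (see above); Dmax, log-log and MLSS-style
  estimators are deliberately out of scope.
* The plateau-onset estimator resolves breakpoints only to the step grid —
  a 50 W protocol cannot localise the plateau more finely than ~0.2 m s^-1^.
* On-water rowing adds technical and environmental determinants the
  ergometer does not have; nothing here should be read as an on-water
  energy cost.
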