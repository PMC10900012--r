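---
title: "Circadian activity rhythm analysis for inpatient wrist actigraphy"
author: "ActiCAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian activity rhythm analysis for inpatient wrist actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ActiCAR)
```

## The problem

Hospitalised elderly patients in rehabilitation wards live under a fixed
timetable: lights on at 07:00, meals at 07:00, 12:00 and 18:00, one morning
and two afternoon therapy sessions of 40-60 minutes, lights out at 22:00.
Their circadian activity rhythm (CAR) — the ~24-hour pattern of physical
activity — can be summarised from wrist-actigraphy recordings that report
epoch-level energy expenditure in METs (multiples of seated resting
expenditure; the device floor is 1.0 MET). ActiCAR implements the complete
analysis chain for such recordings: a two-component periodic regression of
the METs series, extraction of six rhythm descriptors, Cole-Kripke
sleep/wake scoring with nightly sleep metrics, sedentary/light/moderate
activity classification, and a cohort statistics layer. Because real
inpatient recordings of this kind are not publicly deposited, the package
also ships a calibrated synthetic-cohort generator with full ground truth,
which doubles as the test bed for every stage.

## The model

The composite rhythm model is

$$y(t) = M + A_1\cos(\omega_1 t - \theta_1) + A_2\cos(\omega_2 t - \theta_2) + e(t),$$

with fixed angular frequencies $\omega_1 = 2\pi/24$ and
$\omega_2 = 2\pi/12$ rad/hour — a 24-hour and a 12-hour cycle. $M$ (the
mesor) is the rhythm-adjusted mean, $A_k \ge 0$ the component amplitudes,
and $\theta_k \in [0, 2\pi)$ the acrophases. Writing each component as
$a_k\cos\omega_k t + b_k\sin\omega_k t$ makes the model linear, so
`fitHarmonics()` solves it by closed-form least squares (QR decomposition;
no iterative optimiser) and re-expresses $A_k = \sqrt{a_k^2+b_k^2}$,
$\theta_k = \mathrm{atan2}(b_k, a_k)$. $R^2 = 1 - \mathrm{SSR}/\mathrm{SST}$
is the multiple contribution rate. Time is carried internally as real-valued
hours since the subject's first midnight; since the basis is periodic, the
full multi-day record enters the fit directly with no folding (an averaged
clock-day mode is available via `averagedDay = TRUE`; whether multi-day
records should be folded first is a genuinely open design point and
full-record fitting is the default because it uses every epoch's sampling
variance).

The six CAR parameters come from the fitted composite curve over one clock
day: mesor, maximum, minimum, range = maximum − minimum, and the clock
times of the daily maximum and minimum. Because the sum of two harmonics
can have two local maxima per day, `extractCAR()` scans a 60-second grid
for local extrema, brackets each, and polishes it by root-finding on the
analytic derivative (machine precision; ties broken by earliest clock
time). Model adequacy of the 24 h + 12 h pair is checked by
`scanPeriods()`, which fits a single-component model at each candidate
period $T_n = 24/n$, $n = 1 \dots 720$ (down to 2 minutes at 1-minute
epochs) and ranks candidates by $R^2$.

## Sleep scoring

Sleep/wake states come from the published one-minute Cole-Kripke weighted
sum
$D(t) = 0.001\,(106\,c_{-4} + 54\,c_{-3} + 58\,c_{-2} + 76\,c_{-1} +
230\,c_{0} + 74\,c_{+1} + 67\,c_{+2})$,
scored sleep when $D < 1$. The device's count units are proprietary, so
METs are bridged to counts as $c = \max(0, \mathrm{METs}-1)\times s$ with a
calibration scale $s$ (default 15, chosen so that scripted sleep in the
synthetic cohort scores as sleep, with $D \approx 0.85$, and quiet waking
activity scores as wake; all four scoring parameters are configurable).
The main nocturnal bout per night is the longest run of sleep epochs whose
onset falls between 18:00 and 12:00 the next day, allowing internal wake
gaps up to 10 minutes; the paper gives no bout rule, so this one is the
package's own. Bouts shorter than 60 minutes are not credible main sleep
periods and are dropped; nights truncated by the recording boundary are
flagged censored and excluded from averaging. Per night, total sleep time
is the bout duration minus arousal (wake-within-bout) minutes, and sleep
efficiency is $100\,(S - \mathrm{arousal})/S$ with $S$ the nightly sleep
period — the source formula read literally; under these bout definitions it
is algebraically identical to the conventional TST / time-in-bed, so no
separate mode is needed. Metrics are averaged across scoreable nights
(four for a midnight-aligned 5-day record).

## Activity classification

Epochs are classified by METs: sedentary behaviour (SB) below 1.6,
light-intensity physical activity (LIPA) from 1.6 to below 3.0, and
moderate-to-vigorous activity (MVPA) at 3.0 and above. The printed bins
(1.0-1.5 / 1.6-2.9 / 3.0+) leave the open intervals (1.5, 1.6) and
(2.9, 3.0) unassigned for continuous METs; the half-open convention used
here keeps every printed bin edge correctly classified. SB is counted
around the clock; daytime SB excludes 22:00-07:00. Days with under 80%
valid epochs are dropped from averaging, and invalid epochs never count
toward any category.

## Cohort statistics

`cohortReport()` reproduces the comparison grid (sex, diagnosis,
locomotive independence, hypnotics, psychotropics against every CAR and
sleep outcome) and the correlation grid (age, BMI, MMSE, motor FIM, sleep
metrics, SB/LIPA/MVPA). Both Welch's t and the Mann-Whitney test are
reported for every comparison cell, and both Pearson and Spearman
coefficients for every correlation cell, because the source analysis
alternated between them without a fully legible per-cell rule. The
Mann-Whitney p-value is an exact permutation enumeration for combined
n ≤ 20 (midranks handle ties) and a tie-corrected normal approximation
otherwise. Alpha is 0.05 two-sided and no multiplicity adjustment is
applied, mirroring the source analysis; every report header says so.
Regressions are ordinary least squares with the Durbin-Watson statistic
$d = \sum_{t\ge2}(e_t - e_{t-1})^2 / \sum_t e_t^2$ computed on residuals
in subject order (order-dependence is inherent to applying d to a
cross-sectional model) and variance inflation factors from the definition,
$1/(1-R_j^2)$.

## The synthetic cohort

`generatorConfig()` holds the study conditions: 34 subjects, five weekday
records of 1-minute epochs starting at a Monday midnight, covariate
prevalences matching the published cohort (13/34 male, 22/34
cerebrovascular, 10/34 on hypnotics, 2/34 on psychotropics, 20/34
locomotive-independent), and the ward timetable above. Each subject's METs
series is built from:

* a latent two-harmonic rhythm $1 + g\,[c_0 + c_1\cos\omega_1(t - p_1 - \delta)
  + c_2\cos\omega_2(t - p_2 - \delta)]$, scaled by a subject activity
  factor $g \sim$ log-normal, clipped so the smooth rhythm alone never
  crosses the 1.6 METs threshold;
* scheduled bouts: meals (half-sine, fixed times), rehabilitation sessions
  at habitual per-subject slots with a passive elevation plus an
  active-exercise block whose share of the session grows with $g$ at
  absolute light-exercise intensity, brief self-care movement spikes, and
  in-room light-activity blocks whose daily time budget is proportional
  to $g$ — the channel that carries most time above 1.6 METs;
* scripted sleep: nightly bed/wake times drawn around 21:50/06:13 with
  subject- and night-level jitter, 1-4-minute arousals at irregular times
  with a guaranteed 25-minute separation, a smooth evening wind-down and
  morning wind-up, a waking-activity floor of 0.12 METs excess (an awake
  wrist never rests exactly at the device floor), and a night level of
  about 1.085 METs;
* multiplicative log-normal noise on the above-floor component, which
  respects the 1.0 floor without truncation artifacts.

Hypnotics users have the latent rhythm delayed, their morning
rehabilitation participation shifted into the afternoon sessions, and
their free-time activity window pushed later — together delaying the
composite peak by roughly 2.5 hours while leaving sleep timing untouched,
as observed in the source cohort.

Where the study reports a value, the generator default is that value
(sample sizes, prevalences, schedule times, bed/wake means). Where it
does not — bout magnitudes, noise scale, the activity-factor distribution,
arousal load — the constants are free calibration parameters, set once so
the default cohort reproduces the printed cohort summaries (mesor
1.23 ± 0.09 METs, maximum 1.36 ± 0.15, range 0.30 ± 0.15, $R^2$
0.72 ± 0.10, total sleep time 458 ± 69.3 min, sleep efficiency
89.3 ± 6.4%, about 22 h/day sedentary, and a near-linear mesor-SB
relation with Spearman $r \approx -0.94$ and simple-regression
$R^2 \approx 0.91$). Three structural choices matter and were made
deliberately: the 12-hour latent component is phase-aligned with the
schedule's own 12-hour content (otherwise the two cancel and the period
scan no longer selects 12 h as second-best); activity above the LIPA
threshold enters mostly as near-threshold blocks whose daily budget is
linear in $g$ (otherwise the mesor-SB relation curves and the regression
$R^2$ falls well below the printed value); and arousal spacing uses a
hard-core construction (evenly stratified arousals create an artificial
~90-minute ultradian period that competes in the period scan).

Determinism: subject $i$ uses seed $\mathrm{master} + i$, so cohorts are
bit-reproducible and extensible without perturbing earlier subjects. The
ground truth stores the latent parameters, the scripted sleep, and the
population value of the rhythm estimand (the 24 h + 12 h Fourier
projection of the noise-free signal and its composite peak), which is the
correct target for recovery checks: the fitted peak time matches it to
well under 0.01 h on the default cohort, while the latent-only peak
differs from both by design, since the timetable itself shapes the
composite rhythm.

What the generator does not emulate: device-level acceleration mechanics,
off-wrist gaps (validity masks are supported in the analysis path and
tested separately), weekend/family-visit dynamics, naps scored as sleep,
and any within-subject day-of-week structure. Passing calibration tests
therefore show that the analysis chain recovers known structure of
realistic magnitude — not that it would be unbiased on any particular real
device's output.

## Numerical choices and degenerate inputs

* Constant series make $R^2$ undefined; the fit refuses them, as it does
  rank-deficient designs (too few distinct sampling times).
* Valid METs below 1.0 are clamped to the floor with a warning; invalid
  epochs are excluded from fits and never count toward category minutes or
  sleep sums.
* Extremum ties (exactly equal maxima) report the earliest clock time; a
  flat curve (all amplitudes zero) reports both phases as 00:00 with zero
  range.
* CSV gaps that are whole epoch multiples are filled as invalid epochs;
  any other spacing is an error rather than a silent resample.
* Candidate periods shorter than two epochs are skipped with a warning in
  the scan; per-candidate fit failures are recorded, not fatal.
* Clock outputs are reported as decimal hours plus HH:MM strings; bed
  times after midnight are put on a 24+ scale before averaging so 23:30
  and 00:30 average to midnight, not noon.

## Problem sizes used in the test suite

The shipped tests run the full default cohort (34 subjects, five days of
1-minute epochs) once and reuse it across checks; parameter recovery uses
200 independent 5-day series at noise SD 0.1 METs; the extremum oracle
compares 100 random fits against an exhaustive 1-second grid; the
hypnotics power check uses 25 regenerated cohorts. These sizes were chosen
to exercise every claim at the study's own scale while keeping the suite
comfortably fast on one CPU.

## Limitations

The calibration reproduces cohort-level summaries, not subject-level joint
distributions; standard deviations of some derived quantities (notably
sedentary minutes) are narrower than printed. The Cole-Kripke
implementation uses the published generic coefficients, not coefficients
validated for any specific wrist device, and the METs-to-counts bridge is
a linear surrogate. The Durbin-Watson statistic on a cross-sectional
cohort depends on subject ordering; it is reported because the source
analysis reports it, with that caveat attached.
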