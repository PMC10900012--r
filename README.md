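# ActiCAR

Circadian activity rhythm (CAR) analysis for epoch-level wrist-actigraphy
METs recordings, aimed at rehabilitation research on hospitalised elderly
patients. The package covers the full chain from raw epoch series to
cohort statistics:

* **Two-component periodic regression.** The composite model
  `y(t) = M + A1·cos(ω1·t − θ1) + A2·cos(ω2·t − θ2)` with fixed 24-h and
  12-h cycles (`ω_k = 2π/T_k`), fitted by closed-form least squares on the
  full multi-day record. A 720-candidate period scan (`T = 24/n`,
  `n = 1…720`) ranks cycles by R² to justify the 24 h + 12 h choice.
* **Six CAR parameters** from the fitted composite curve: mesor, maximum,
  minimum, range, and the clock times of the daily maximum and minimum
  (grid search plus analytic-derivative refinement).
* **Cole-Kripke sleep scoring** (published 1-minute weighted-sum rule),
  main-sleep-bout detection, and nightly total sleep time, sleep
  efficiency, bed and waking times averaged over nights.
* **SB/LIPA/MVPA classification** by METs cut-points (<1.6 / 1.6–<3.0 /
  ≥3.0), daily totals and the daytime-sedentary total (07:00–22:00).
* **Cohort statistics**: Welch / Mann-Whitney comparisons (exact
  permutation p for small samples), Pearson / Spearman correlations,
  single and multiple regression with Durbin-Watson and variance
  inflation diagnostics.
* **A calibrated synthetic-cohort generator** that emulates 5-weekday
  inpatient recordings under a fixed ward schedule, with full ground
  truth — the package's test bed, since comparable clinical recordings
  are not publicly deposited.

The central classes are S4 (`EpochSeries`, `HarmonicFit`,
`CARParameters`, `SleepWakeSeries`, `ActigraphyCohort`) with accessor
functions and validity checks. See the methods vignette
(`vignettes/acticar-methods.Rmd`) for the model, the generator's
calibration and its limitations.

## Worked example

```r
library(ActiCAR)

cohort <- generateCohort(generatorConfig())   # 34 subjects, 5 weekdays
es <- cohortSeries(cohort)[["S01"]]

fit <- fitHarmonics(es, periods = c(24, 12))
fit
#> HarmonicFit: 2 component(s), 7200 epochs
#>   mesor M = 1.2412 METs, R^2 = 0.674
#>   T = 24 h: A = 0.2025 METs, theta = 2.9678 rad (peak 11:20)
#>   T = 12 h: A = 0.0788 METs, theta = 5.4517 rad (peak 10:25)

extractCAR(fit)
#> CAR parameters:
#>   mesor   1.2412 METs
#>   maximum 1.5189 METs at 10:46 (10.774 h)
#>   minimum 1.0613 METs at 02:17 (2.287 h)
#>   range   0.4577 METs; R^2 = 0.674
```

Subject S01's activity rhythm averages 1.24 METs, peaks mid-morning at
1.52 METs, and is quietest shortly after 02:00; the two-cycle model
explains 67% of the epoch-level variance. Sleep and activity summaries
come from the same series:

```r
sleepSummary(detectMainSleep(coleKripke(es)))
#>  total_sleep_time_min sleep_efficiency_pct waking_time_h bed_time_h n_nights
#>                399.25             95.23346      5.191667   22.20833        4

summarizeActivity(es)
#>  sb_min_per_day daytime_sb_min_per_day lipa_min_per_day mvpa_min_per_day n_days
#>          1314.6                  774.6            125.4                0      5
```

This subject goes to bed around 22:13, wakes just past 05:11, sleeps
399 min/night at 95% efficiency, and is sedentary for ~21.9 h/day. The
full pipeline (validate → fit CAR → score sleep → classify activity →
cohort statistics) runs in one call and reproduces the cohort-level
picture:

```r
res <- runPipeline(runConfig())
ct <- res$cohortTable
#> cohort means: mesor 1.23, maximum 1.50, range 0.44, R2 0.68
#> TST 456.3 min, efficiency 91.7%, SB 1316 min/day

res$regressions$mesor_on_sb
#> Regression on mesor (n = 34): R^2 = 0.903, F = 299.023, p = 8.538e-18
#>                Estimate Std. Error  t value Pr(>|t|)
#> (Intercept)      2.3720     0.0660  35.9283        0
#> sb_min_per_day  -0.0009     0.0001 -17.2923        0
#> Durbin-Watson d = 1.577
```

The strong negative mesor-on-sedentary-time regression (each extra
sedentary hour lowers the rhythm mean by ~0.05 METs) is the cohort's
central association. `runPipeline(..., outDir = "run")` additionally
writes per-subject TSVs, the comparison/correlation report bundle, a
manifest JSON that reproduces the run, and optional per-subject curve
plots. A thin command-line wrapper lives in
`inst/scripts/run-pipeline.R`; the full default configuration is in
`inst/extdata/default_config.yaml`.

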