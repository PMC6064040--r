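# thyrowear

Wearable-device resting heart rate (WD-rHR) as a digital marker of thyroid
function.

Thyrotoxicosis raises resting heart rate, but clinic pulse readings are
one-off snapshots. A wrist tracker logs heart rate and step counts all day;
`thyrowear` turns those intraday logs into a visit-level resting-heart-rate
marker and quantifies how well it tracks serum free T4 across the treatment
course of thyrotoxic patients. It is aimed at biostatisticians and digital
health researchers who want a tested, reproducible implementation of this
kind of pipeline.

The package provides:

* **Device-log I/O** — a documented JSON dialect for per-day intraday
  heart-rate and step samples (`read_day_log()`, `write_day_log()`,
  schema in `inst/extdata/device-log-schema.json`), with validation of
  every format invariant.
* **Rest-window extraction** — a minute *m* is *resting* when a heart-rate
  sample exists at *m* and step counts are recorded and zero throughout
  the closed 15-minute lookback window [*m* − 15, *m*]; the daily rHR is
  the median over resting minutes; the visit-level WD-rHR is the mean of
  the daily values over the 5 days strictly before the clinic visit
  (`qualifying_minutes()`, `daily_rhr()`, `visit_wd_rhr()`,
  `extract_all()`). Non-wear minutes never certify rest.
* **Clinical scoring** — Hyperthyroidism Symptom Scale totals (10 items,
  0–40), thyroid-status labels against reference ranges (overt /
  subclinical / euthyroid / other), the binary thyrotoxicosis outcome
  (free T4 ≥ 1.8 ng/dL), and 1-SD standardization.
* **GEE inference** — linear and binary-logistic generalized estimating
  equations written from first principles: Fisher scoring on
  Σᵢ Dᵢᵀ Vᵢ⁻¹ (yᵢ − μᵢ) = 0 with an exchangeable (or independence)
  working correlation re-estimated by moments, robust sandwich variance,
  and Wald 95% CIs. Effects are reported per 1 SD of the standardized
  marker; the logistic fit reports the odds ratio e^β.
* **Descriptive tests** — pooled-variance t, Mann-Whitney, chi-square,
  two-sided Fisher exact, Friedman, and repeated-measures ANOVA with
  Greenhouse-Geisser correction.
* **A calibrated synthetic-cohort generator** — subjects, treatment-driven
  free-T4 trajectories, minute-level heart rate (circadian rhythm,
  activity bouts with first-order recovery, measurement noise, non-wear),
  on-site visit measurements and symptom scores, reproducible from a seed
  (`generator_config()`, `generate_study()`).
* **Pipeline orchestration** — `run_all()` / `run_simulate()` /
  `run_extract()` / `run_analyze()` / `run_report()` plus a thin CLI
  (`inst/scripts/thyrowear.R`) over YAML configs.

## Worked example

Simulate the default study (28 thyrotoxic patients, 10 controls, 3 monthly
visits, 5 wear days per visit), extract WD-rHR, and fit the standardized
association models:

```r
library(thyrowear)
cfg <- run_config(generator = generator_config(seed = 20240101L))
res <- run_all(cfg)
res$analysis$linear_gee[, 1:7]
#> # A tibble: 6 × 7
#>   analysis_set     parameter  sd_unit estimate ci_low ci_high  p_value
#>   <chr>            <chr>        <dbl>    <dbl>  <dbl>   <dbl>    <dbl>
#> 1 thyrotoxic_only  hss           7.81    0.776  0.637   0.915 7.66e-28
#> 2 thyrotoxic_only  onsite_rhr   11.8     0.420  0.104   0.737 9.25e- 3
#> 3 thyrotoxic_only  wd_rhr       10.4     0.624  0.271   0.978 5.37e- 4
#> 4 all_participants hss           7.35    0.689  0.550   0.829 2.86e-22
#> 5 all_participants onsite_rhr   13.3     0.381  0.147   0.615 1.39e- 3
#> 6 all_participants wd_rhr       10.7     0.530  0.242   0.819 3.19e- 4
```

Each row is one marginal linear GEE of free T4 (ng/dL) on one standardized
marker: `sd_unit` is the pooled SD defining "1 SD" (about 11 bpm of
wearable rHR here), `estimate` the change in free T4 per 1-SD increase of
the marker with its robust 95% CI. In this simulated cohort a 1-SD increase
in wearable rHR corresponds to about 0.53 ng/dL higher free T4 across all
participants — and the wearable marker, an average over hundreds of resting
minutes, shows a tighter association than the single on-site pulse reading
(0.38 per SD), which carries the visit effect. The logistic table
(`res$analysis$logistic_gee`) reports odds ratios for free T4 ≥ 1.8 ng/dL
per 1-SD increase in the same layout, and `res$analysis$baseline`,
`res$analysis$trajectory` and `res$analysis$figure_data` hold the two-group
comparisons, per-visit means with repeated-measures tests, and plot-ready
mean/CI data.

At the single-day level:

```r
log <- res$study$logs[[1]]
log
#> <device_day_log> subject S0001, 2024-01-01: 1294 heart samples, 1294 step samples
daily_rhr(log)
#> # A tibble: 1 × 4
#>   subject_id date         rhr n_rest_minutes
#>   <chr>      <date>     <dbl>          <int>
#> 1 S0001      2024-01-01  96.8            122
```

122 of 1440 minutes passed the activity gate on this day (the rest fall
inside bout shadows or non-wear gaps), and their median — 96.8 bpm — is the
day's resting heart rate.

The same pipeline runs from the shell:

```sh
Rscript inst/scripts/thyrowear.R all --seed 7 --output-dir out/
```

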