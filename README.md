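# oculorhythm

Chronotype-anchored cosinor rhythmometry of ocular biometry and salivary
melatonin.

The eye's dimensions oscillate over the day: axial length (AL), choroidal
thickness (ChT), anterior chamber depth (ACD), lens thickness (LT),
retinal thickness (RT), vitreous chamber depth (VCD) and intraocular
pressure (IOP) all show ~24-hour rhythms that appear synchronised with
melatonin secretion, and seasonal shifts in their phase relationships
have been linked to the direction and degree of axial eye growth in young
adults. This package implements the analysis pipeline for repeated-
measures designs in which every measurement epoch is anchored to the
individual's habitual wake and sleep times (HWT/HST) rather than to the
wall clock, for researchers in myopia, chronobiology and ocular
physiology.

At its core is the fixed-period cosinor

> y(t) = M + A sin(2π (t + φ) / 24)

with t in hours relative to HST, fitted per individual by least squares
on the sin/cos basis and per population by a linear mixed model
(`lme4`) with subject random effects; phase is reported as the acrophase
(time of fitted peak) in (−12, 12] hours relative to HST, or converted to
standard clock time. On top of the cosinor sit:

* analytic dim-light melatonin onset (DLMO) from the log-scale melatonin
  fit: DLMO = (24/2π)·asin((ln 3 − M)/A) − φ, threshold 3 pg/mL;
* circular season comparison (ΔMESOR, Δamplitude, Δacrophase with
  paired tests and Holm adjustment; phase relationships and antiphase
  distance);
* axial-growth classification against month-scaled coordinated-growth
  thresholds (annual 0.030–0.089 mm; 7-month 0.017–0.052 mm) with
  regression/ANOVA association statistics;
* a synthetic-cohort generator reproducing the design's hierarchical
  structure (subject-level MESOR/amplitude/acrophase effects shared
  across seasons, log-normal melatonin, per-epoch noise), calibrated to
  published population estimates and used throughout the test suite;
* a deterministic end-to-end pipeline (`run_pipeline()`) writing CSV
  intermediates and a run manifest.

Bundled reference tables (`reference_rhythm_estimates()`,
`reference_clock_times()`, `reference_growth_table()`) carry the
published population estimates for a 24-participant winter/summer cohort
at 60°N, used as simulation defaults and worked-example inputs.

## Worked example

Simulate a two-season cohort at the published winter/summer truth, fit
the melatonin rhythm, and derive the onset:

```r
library(oculorhythm)

truth  <- simulation_truth(n_participants = 24, seasons = c("W1", "S"),
                           seed = 42)
cohort <- generate_cohort(truth)
cohort
#> <cohort_table> 24 participants, 3024 measurements (S, W1)

mel <- subset(cohort$measurements, parameter == "MEL" & season == "W1")
fit <- fit_population(mel, log_scale = TRUE, parameter = "MEL",
                      season = "W1")
fit$population
#> <cosinor_fit population MEL W1> MESOR 1.011, amplitude 3.185, acrophase 4.17 h

onset <- dlmo_relative(fit$population)
onset
#> <dlmo_result> HST -1.72 h (threshold 3 pg/mL)
dlmo_clock(onset, "00:08")
#> [1] "22:25"
```

The population melatonin rhythm in this simulated winter peaks 4.17 h
after habitual sleep time (truth: 3.99 h) with log-scale MESOR 1.01
(truth 0.87) and amplitude 3.19 (truth 3.155); melatonin rises through
3 pg/mL 1.7 h before habitual sleep time, i.e. at 22:25 for a person
whose HST is 00:08 — a few minutes from the published winter onset
(22:20), as expected for a single simulated cohort of 24.

Worked-example arithmetic on the bundled reference estimates
(no simulation involved):

```r
seasonal_shift_table()[c(1, 3, 6), c("parameter", "shift_min", "clock_w1", "clock_s")]
#> # A tibble: 3 × 4
#>   parameter shift_min clock_w1 clock_s
#>   <chr>         <dbl> <chr>    <chr>
#> 1 MEL             -51 04:07    03:16
#> 2 ACD             -48 02:34    01:46
#> 3 AL              -61 15:20    14:19

scale_thresholds(months = 7)$bounds
#> [1] 0.017 0.052
table(classify_growth(reference_growth_table()$dal_w1_w2[2:9], "annual"))
#>  shortening   no_growth coordinated accelerated
#>           0           2           5           1
```

The winter→summer acrophase advances (melatonin 51 min, ACD 48 min, AL
61 min) and the growth classification of the published annual table
(2 no-growth / 5 coordinated / 1 accelerated among participants 2–9)
match the published values exactly.

A complete run — simulate, fit every parameter × season, onset table,
season comparison, growth classification, report:

```r
out <- run_pipeline(run_config("runs/demo", seed = 1,
                               n_participants = 24,
                               seasons = c("W1", "S")))
head(out$report)
```

or from the shell:

```sh
Rscript scripts/oculorhythm.R run --out runs/demo --seed 1 --n 24 --seasons W1,S
```

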