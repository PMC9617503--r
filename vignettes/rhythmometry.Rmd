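---
title: "Cosinor rhythmometry of ocular biometry and melatonin: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cosinor rhythmometry of ocular biometry and melatonin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculorhythm)
```

## The problem

The human eye is not a static organ over the day: axial length (AL),
choroidal thickness (ChT), anterior chamber depth (ACD), lens thickness
(LT), retinal thickness (RT), vitreous chamber depth (VCD) and intraocular
pressure (IOP) all oscillate with an approximately 24-hour period, and
these rhythms are thought to be coupled to the central circadian clock as
read out by salivary melatonin (MEL). Because individuals differ in
chronotype, sampling at fixed wall-clock times confounds the rhythm with
the person's sleep timing. The design this package analyses therefore
anchors every measurement epoch to the individual's habitual wake time
(HWT) and habitual sleep time (HST): two daytime epochs (`HWT+1`,
`HWT+4`) and six evening epochs (`HST-4` ... `HST+1`), giving eight
samples per parameter per day (seven for melatonin, which has no midday
sample). All analysis time coordinates are hours relative to HST, with 0 =
HST; morning epochs are large negative values (about -17 to -11).

## The cosinor model

Each series is modelled as a fixed-period sinusoid

$$y(t) = M + A \sin\!\big(2\pi (t + \varphi) / 24\big),$$

where $M$ is the MESOR (rhythm-adjusted mean), $A \ge 0$ the amplitude
(half the peak-to-trough excursion) and $\varphi$ the phase parameter.
We report phase as the **acrophase** — the time of the fitted peak, $6 -
\varphi$ wrapped into $(-12, 12]$ hours relative to HST — which is the
convention under which published estimates for this design are tabulated.
Melatonin is fitted on the natural-log scale, which linearises its
near-exponential evening rise.

Because the period is fixed, the model is linear in
$(\,M, \beta_s, \beta_c\,)$ with $\beta_s = A\cos(\omega\varphi)$,
$\beta_c = A\sin(\omega\varphi)$, $\omega = 2\pi/24$:

* `fit_individual()` — ordinary least squares per subject series (exactly
  equivalent to nonlinear least squares here, but convex and
  deterministic). At least 4 observations at 3 distinct times mod 24 are
  required for the 3 free parameters.
* `fit_population()` — a linear mixed model on the same basis
  (`lme4::lmer`) with independent per-subject random effects on the
  intercept and both coefficients, REML estimation. Fixed effects are
  transformed back to $(M, A, \text{acrophase})$. Confidence intervals,
  when requested, come from a nonparametric bootstrap over participants
  (the subject is the exchangeable unit), rather than asymptotic mixed-model
  intervals whose assumptions we cannot verify at $n \approx 24$.

Two subtleties deserve a note:

* **Fixed-effect amplitude attenuation.** When subjects genuinely differ
  in phase, the mean of their coefficient vectors is shorter than the
  typical subject's amplitude (by a factor
  $\approx e^{-(\omega\sigma_\varphi)^2/2}$). At the phase dispersions
  implied by the reference cohort this attenuation is below 2% and we
  accept it; a nonlinear mixed parameterisation in $(M, A, \varphi)$
  avoids it in principle but showed clearly worse small-sample bias when
  we benchmarked it, so the linearised route is the default and only
  estimator.
* **Shrunken per-subject estimates.** `fit_population()` also returns
  per-subject fits built from the mixed model's conditional modes
  (`$subject`, tagged `estimator = "blup"`). Per-individual quantities
  that feed further analysis — seasonal contrasts, melatonin onset per
  person, growth deltas — use these by preference: partial pooling
  suppresses the large phase noise that unpooled 8-point fits exhibit for
  low-amplitude parameters such as AL (residual-driven phase error of an
  unpooled fit is about 0.65 h at our default noise level, and has heavy
  tails). Unpooled OLS fits remain available as `$individual`.

A flat series ($A$ below $10^{-12}$) has no identifiable phase; such fits
are flagged `degenerate` and report acrophase 6 by convention so that
downstream code never branches on NA.

### Testing for diurnal variation

`diurnal_variation_test()` computes the F test for the epoch factor in a
subject-blocked two-way layout (subject as random block, epoch fixed) —
the classical repeated-measures ANOVA, which is the exact reduction of a
mixed model with a subject random intercept for this balanced design. It
is exact under normality (its type-I error at $\alpha = 0.05$ is verified
by simulation in the test suite) and cheap enough to be simulated
thousands of times. A within-subject permutation p-value (epoch labels
shuffled inside each subject) is available as a distribution-free
cross-check.

## Melatonin onset (DLMO)

Dim-light melatonin onset is the evening time at which salivary melatonin
rises through 3 pg/mL. Given the log-scale cosinor, the onset solves the
fitted curve analytically:

$$\mathrm{DLMO} = \frac{24}{2\pi} \arcsin\!\Big(\frac{\ln 3 - M}{A}\Big) - \varphi .$$

The principal arcsin branch selects the *rising* crossing, which always
lies in the half-period before the acrophase. Natural logarithms are used
throughout: with the bundled reference estimates this yields plausible
peak melatonin ($e^{0.87 + 3.155} \approx 56$ pg/mL) and reproduces the
published onset clock times to within rounding of the inputs; base-10
logs do not. The onset is undefined (flagged, never NaN) when
$|(\ln 3 - M)/A| > 1$, i.e. the curve never crosses threshold. The
analytic root is verified in the tests against a dense scan of the fitted
curve over 1000 random fits.

## Season comparison and circular conventions

Acrophases live on a 24-h circle. All phase differences use
`circular_diff(a, b)` = $a - b$ wrapped into $(-12, 12]$, negative values
meaning *a* peaks earlier (phase advance); exact opposition maps to +12
by convention so the function is total. `phase_relation()` reports the
separation of two rhythms together with its distance from exact antiphase
(12 h) — the quantity of interest for the AL/ChT relationship.

`compare_seasons()` pairs each participant's fits across two seasons and
summarises per-parameter changes in MESOR, amplitude and acrophase
(circularly differenced). Each quantity gets a paired t-test, replaced by
the Wilcoxon signed-rank test (zeros dropped, the standard convention)
when Shapiro-Wilk rejects normality of the differences at 0.05; p-values
are Holm-adjusted across parameters within each quantity. Linear paired
tests on wrapped differences are appropriate here because observed
seasonal shifts (about an hour) are far from the ±12 h wrap point.
Identical inputs produce zero deltas with p = 1 and a `degenerate` flag
rather than NaN.

## Growth classification

Published annual bounds for *coordinated* axial growth in this age group
are 0.030–0.089 mm over 12 months. `scale_thresholds()` rescales them to
an arbitrary interval by `months/12` and rounds to 3 decimals **with
exact halves rounded down**: $0.030 \times 7/12 = 0.0175 \to 0.017$ and
$0.089 \times 7/12 = 0.05192 \to 0.052$, the only rounding rule that
reproduces both published 7-month bounds (truncation would give 0.051,
round-half-up 0.018). The seven-month scheme classifies
decelerated / coordinated / accelerated with coordinated on
$[0.017, 0.052)$; the annual scheme distinguishes shortening
($\le 0$), no growth $(0, 0.030]$, coordinated $(0.030, 0.089]$ and
accelerated ($> 0.089$). The boundary at exactly 0.017 is ambiguous in
the source material (the printed category *ranges* overlap at the cut
points); we treat the cut points as the definition and make boundary
behaviour explicit in tests.

Interval changes use *time-matched* axial length: each season's fitted
sinusoid is evaluated at a common set of reference times (default the six
evening epochs, averaged), so that seasons measured at different clock
times are compared at the same circadian phase. ChT change uses the MESOR
difference, matching how seasonal choroidal change is tabulated in the
reference material. `association_stats()` runs the standard downstream
models: simple regressions of $\Delta AL$ on $\Delta ChT$ and on the AL
phase shift, and a one-way ANOVA across growth categories with Tukey HSD.

## The synthetic cohort generator

`generate_cohort()` emulates the study design so that every stage is
testable without any external data: per participant a habitual sleep time
(normal around 00:08, SD 1 h — the reference cohort's anchor), a waking
day of 16 ± 0.75 h, the eight epoch times derived exactly as for real
data, and per parameter $\times$ season sinusoidal values with
subject-level parameters around the population truth:

* MESOR and acrophase effects: independent normals (acrophase wrapped);
* amplitude effects: *multiplicative lognormal*, moment-matched to the
  stated mean and SD. An additive normal truncated at zero — the obvious
  alternative — hands a noticeable fraction of subjects a near-zero
  amplitude and therefore an unidentifiable phase at realistic amplitude
  CVs, a pathology real diurnal biometry does not show; a lognormal is
  the standard model for a strictly positive scale parameter;
* subject effects are drawn once and shared across seasons (the same
  people return), so paired seasonal contrasts have the correlation
  structure of the real design;
* residual noise is Gaussian per epoch; melatonin is generated on the
  natural-log scale and exponentiated, so values are strictly positive.

**Calibration.** The study prints population estimates and 95% CIs but no
variance components, so the package calibrates once, as follows, and the
defaults are not revisited: residual SD is 0.3 × amplitude per parameter
(for AL this is ~0.006 mm, consistent with the biometer's quoted
repeatability; for log-melatonin ~0.95, a realistic assay-plus-biology
spread). Between-subject SDs then follow from the reference CIs by
removing the residual-driven estimation variance before scaling:
$\mathrm{sd}_b = \sqrt{\max(0,\; n\,\mathrm{SE}_{CI}^2 - v_{resid})}$,
with $v_{resid}$ the per-subject OLS variance of each quantity computed
from the actual information matrix of the epoch design (the clustered
design — six of eight points within five hours — makes these variances
approximately 1.8× larger than uniform-sampling formulas suggest, so the
exact matrix matters). Under this calibration simulated population
standard errors reproduce the reference CI widths by construction.

The per-subject truth table is attached to every generated cohort
(`cohort_truth()`), so any downstream estimate can be scored against
truth. `generate_growth_cohort()` adds per-participant interval changes
in AL (MESOR and acrophase) and ChT (MESOR) on top of a base cohort whose
population AL/ChT values are held constant across seasons — the
per-participant growth truth is then the *only* seasonal driver of those
parameters, and interval additivity
($\Delta_{W1\text{-}S} + \Delta_{S\text{-}W2} = \Delta_{W1\text{-}W2}$)
holds exactly by construction. Regression structures linking $\Delta AL$
to $\Delta ChT$ and to phase shift are specified by slope and noise SD;
`noise_sd_for_r2()` converts a target population $R^2$ into the required
noise SD.

**What passing tests do and do not show.** The generator produces ideal
sinusoids plus Gaussian noise with the stated hierarchy. It does not
emulate assay floor effects in daytime melatonin, non-sinusoidal rhythm
shapes, missing epochs, actigraphy error in the HST anchor, or
measurement-session autocorrelation. Parameter-recovery results therefore
validate the estimation machinery under the model's own assumptions, not
robustness to those departures.

## Problem sizes and numerical choices

Simulation-based checks in the test suite and acceptance script use the
study's own scale — cohorts of n = 24 with 8 epochs — at replicate counts
chosen to make Monte-Carlo error small relative to the tolerance being
asserted: 500 cohorts for population parameter recovery (MESOR and
amplitude bias within 2%, acrophase MAE under 0.2 h), 1000 for the
diurnal test's type-I error (0.05 ± 0.02 band), 200 for recovery of an
injected 1-hour AL phase advance (detected with Holm-adjusted
significance in ≥ 90% of cohorts; grand-mean shift within 0.2 h). Brute
force oracles (an (M, A, acrophase) lattice search for the cosinor; a
1-ms dense scan for the onset) are kept independent of the closed-form
code paths they verify.

Other numerical conventions: clock strings are `HH:MM` (fractional
minutes tolerated on input, rendering rounds to the nearest minute);
retinal thickness is stored in µm as tabulated and converted to mm only
inside `derive_vcd()`; all randomness flows from a single integer seed
per generator call; bootstrap and permutation procedures take explicit
seeds. Degenerate situations are deterministic: flat fits report
acrophase 6 with a flag, undefined onsets are flagged rather than NaN,
identical-season comparisons return p = 1, and a failed mixed-model fit
falls back to the two-stage estimator (mean of individual coefficients)
with a `fallback` flag.

## Known limitations

* The acrophase paired test treats wrapped differences linearly; for
  shifts approaching ±12 h a genuinely circular test would be needed.
* The fixed-effect amplitude is mildly attenuated under phase dispersion
  (see above); at the calibrated dispersions this is < 2% and is covered
  by the recovery tests.
* Per-subject melatonin onsets inherit the quality of the subject's
  log-melatonin fit; with only 7 points the shrunken fits are strongly
  preferred.
* The morning-epoch time anchor accepts `t_rel` as given in the input
  table; whether a self-reported or actigraphy-derived wake time produced
  it is the data producer's responsibility.
* The annual growth analysis of the reference design rests on 10
  participants; the bundled table is reproduced for worked examples, not
  re-estimated.
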