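---
title: "Functional time ratios from limit-of-stability CoP recordings: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional time ratios from limit-of-stability CoP recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftrcop)
```

This vignette is the package's own account of the method it implements: the
task geometry, the dwell-time statistic, the reliability and classification
machinery around it, the simulator that stands in for patient data, and the
numerical and design choices that were genuinely open.

## The task and its geometry

A limit-of-stability (LoS) trial starts with 5 s of quiet stance, from which
the *home position* is estimated as the mean CoP. In a separate calibration
step the subject leans as far as possible forward, backward, left and right;
the maximum excursion per direction over the recorded attempts, times 0.75,
is that subject's *target distance*. Eight targets sit on the rays at 45°
steps from home: the four cardinal targets exactly at their direction's
target distance, the four diagonal targets where the 45° ray meets the
boundary of the rectangle whose half-extents are the per-direction target
distances. We use the ray–rectangle intersection because the analysis itself
reduces the octagonal movement area to a rectangle; an elliptical
interpolation between adjacent cardinal distances is available via
`place_targets(diagonal = "ellipse")` for users who prefer a smooth boundary.

Scoring replays the protocol against the recorded trajectory
(`detect_hits()`): each target phase ends at the first sample within the hit
radius of the blinking target — at most 10 s after phase onset, inclusive —
or at the timeout; either way the subject must then stay within the home
radius continuously for 5 s before the next target lights up. The total
score is the number of targets hit (0–8). Two protocol constants are not
physically measurable from data and are documented defaults: the hit radius
(10% of the mean cardinal target distance — a stand-in for the on-screen
target size, configurable) and the rule that a timeout advances to the home
phase (the trial structure is fixed at eight targets either way).

## The functional time ratio

The analysed signal is the task portion of the trial: the first 5 s of quiet
stance are removed, time is re-zeroed, and the remainder is low-pass
filtered. Three co-centric rectangles (*rectangular functional areas*) are
centred on the per-axis **median** of the analysed samples — the median, not
the mean, so that brief excursions do not drag the centre — with
per-direction boundary distances at 33%, 67% and 100% of the reference
distance. The three **regions** are disjoint bands: region 1 is the inner
rectangle, region 2 the 33–67% band, region 3 the 67–100% band. The
functional time ratio of region *i* is the percentage of analysed samples
falling in region *i*; `ftr_out` tracks samples beyond the outermost
rectangle, so `ftr1 + ftr2 + ftr3 + ftr_out = 100` is an exact conservation
law (enforced to 1e-9 in the tests). `FTR_1/2 = FTR_1 / FTR_2` is the
headline index.

Choices worth stating explicitly:

* **Disjoint bands, not nested areas.** Under a nested (cumulative) reading
  the outermost ratio would always be ≈100% and the three ratios could not
  sum to ≈100, which is how the measure's published reliability figures
  behave; the band reading is the only consistent one.
* **Reference distance.** The 100% boundary defaults to the calibrated
  target distance (75% of maximal excursion), i.e. the rectangle the targets
  themselves span; `build_rfas(reference = "max")` uses the raw maximal
  excursion instead.
* **Literal percentages.** The levels are exactly 0.33/0.67/1.00, not 1/3
  and 2/3.
* **Boundaries closed inward.** A sample exactly on the 33% boundary counts
  as region 1. On continuous data this is a measure-zero choice; on grid
  data it is deterministic.
* **Time = sample fraction.** Uniform sampling makes dwell time proportional
  to sample counts; no interpolation of boundary crossings is attempted.
* **Denominator.** Total time is the whole trimmed trial, including home
  holds and timeout periods; nothing in the task definition justifies
  excising them, and the home-hold share is informative (it is inner-region
  time for stable subjects).
* **Degenerate ratio.** If no sample falls in region 2, `ftr12` is `Inf`
  with `ftr12_degenerate = TRUE` — flagged, not an error, because downstream
  the decision rule maps it to the low-FoF side anyway.
* **Aggregation.** The three repetitions of a condition are averaged
  component-wise; the aggregated index is the ratio of mean FTR₁ to mean
  FTR₂ by default (`ratio = "mean_of_ratios"` is the alternative). The RFA
  centre is the per-repetition median; `pooled_median = TRUE` pools the
  repetitions of a condition instead.

## Preprocessing

The filter is a 4th-order Butterworth low-pass at 10 Hz, applied forward and
backward (zero phase), because a phase lag would shift dwell intervals in
time. Consequences and choices:

* "4th order" is the order of the designed prototype *per pass*; the
  magnitude response after both passes is its square (8th-order effective),
  so the gain at the cutoff is 1/2, not 1/√2. The tests pin this analytic
  value (±0.02).
* Edges are handled by odd (point-reflection) padding of 3·(order+1) samples
  plus steady-state initial conditions, so a constant signal passes exactly
  (DC deviation < 1e-9 is a tested contract) and start-up transients do not
  leak into dwell counts.
* The stated processing order is trim-then-filter, with the home position
  computed from the *raw* first 5 s; `filter_before_trim = TRUE` and
  `home_from = "filtered"` expose the alternatives, which differ only in a
  few samples near the trim boundary.
* Non-uniformly sampled input is rejected, not resampled; the sampling rate
  is a per-trial property (balance boards and force plates run at different
  rates) and is inferred from timestamps when not declared.

## Reliability and correlation machinery

`icc_2k()` computes the two-way random-effects, absolute-agreement,
average-of-k-measures intraclass correlation ICC(2,k) from the two-way ANOVA
mean squares, with k = 3 repetitions in this design. The 95% CI uses the
standard F-interval for the single-measure agreement coefficient with
Satterthwaite degrees of freedom, stepped up to k measures by
Spearman–Brown; the implementation reproduces an independent reference
implementation to 1e-9 on a frozen fixture. The standard error of
measurement defaults to `SD_pooled * sqrt(1 - ICC)` — the usual companion to
ICC-based SEM — with `sem_formula = "ms_error"` (`sqrt(MS_E)`) as the
documented alternative, since the convention is not universal. Interpretation
bands: ICC < 0.40 poor, 0.40–0.75 acceptable, ≥ 0.75 high; %SEM > 20 poor,
10–20 acceptable, ≤ 10 high.

`correlate()` reports Pearson or Spearman coefficients with the conventional
strength bands on |r| (< 0.20 negligible, 0.20–0.34 weak, 0.35–0.50
moderate, > 0.50 strong); `method = "auto"` delegates a Shapiro–Wilk
normality gate at α = 0.05 and falls back to Spearman when either variable
rejects. `collinearity_screen()` flags predictor pairs with |r| strictly
above 0.80 — the screen that motivates replacing the strongly
anti-correlated FTR₁ and FTR₂ with their ratio in the first place.

## Classification machinery

`fit_logistic()` is maximum likelihood via `stats::glm` (IRLS), reported as
an odds ratio with a Wald 95% CI; complete or quasi-complete separation is
detected and flagged (`converged = FALSE`, infinite CI) rather than raised,
because a separable cohort is a legitimate outcome at these sample sizes.
`roc_analysis()` computes the AUC by the rank (Mann–Whitney) formulation
with tie correction — tested against brute-force pair counting on hundreds
of random datasets — thresholds at the observed score values, an
orientation chosen so AUC ≥ 0.5 (for FTR_1/2, *lower* values indicate the
high-FoF class), and a seeded stratified bootstrap CI (2000 resamples by
default; a DeLong interval is a natural extension point). The Youden-optimal
cutoff maximises J = sensitivity + specificity − 1 over observed values,
breaking ties by higher sensitivity and then the more extreme cutoff, and is
reported with inclusive orientation (`<= cutoff`), matching how such
cutoffs are printed clinically. `caic()` defaults to the small-sample AICc
(−2lnL + 2k + 2k(k+1)/(n−k−1)); "corrected AIC" sometimes denotes Bozdogan's
consistent criterion instead, so `variant = "consistent"` is provided — only
the model *ranking* feeds the pipeline, and at fixed k and n the two agree.

`crossvalidate()` uses stratified folds (preserving the class imbalance in
each fold) from a seeded shuffle, refits the logistic model per fold and
re-derives the operating point from the training ROC — an honest estimate;
`reuse_global_cutoff = TRUE` reuses the full-sample cutoff instead. One
deliberate deviation: the held-out decision boundary is the *midpoint*
between the training Youden-optimal probability threshold and the adjacent
observed value, not the inclusive observed-value cutoff. An observed-value
boundary cannot generalise past the most extreme training observation (a
perfectly separable dataset would still incur CV errors whenever that
observation is held out); the midpoint rule classifies scores falling inside
the training gap sensibly while changing nothing when held-out scores
coincide with training values. Reported (non-CV) cutoffs remain at observed
values. Note that the full-sample "overall accuracy" at the Youden cutoff
and the cross-validated error are different procedures and are reported
side by side, clearly labelled.

`apply_threshold()` is the fixed clinical rule: `FTR_1/2 <= 2.83` at ground
level (`<= 2.71` at 40 cm) classifies as high fear of falling, inclusively.

## The simulator

The simulator exists so that every pipeline stage has a deterministic,
seedable test harness. It has two modes.

**Dwell mode** (`simulate_dwell_trajectory()`) places exactly
`round(p_i * n)` samples uniformly inside each RFA band and shuffles them in
time: with a *fixed* RFA centre the computed FTRs are forced up to rounding,
which makes the time-ratio statistic exactly testable. When the RFAs are
instead re-centred on the trajectory median downstream, the recovered values
shift slightly — which is why fixed-centre mode is the exactness harness and
realistic mode only feeds end-to-end runs.

**Trial mode** (`simulate_los_trial()`) generates the full protocol: quiet
stance, then eight target phases of critically damped second-order
point-mass reaches toward an aim point, with band-limited 4–7 Hz tremor
added (below the 10 Hz cutoff, so filtering is exercised meaningfully, but
above the reach dynamics). A per-target Bernoulli decides whether the aim
point is the target (with small endpoint error) or a mid-range shortfall at
45–52% of the target distance — the hover behaviour of a fearful subject.
Hits are then determined *geometrically from the generated trajectory with
the same rule the scorer uses*, so ground truth and replay agree by
construction rather than by bookkeeping. Two generation details exist purely
to keep that agreement stable under filtering: after the first boundary
touch the reach keeps sinking toward the aim point for 0.4 s (otherwise the
minimum target distance equals the radius exactly and smoothing flips the
hit), and home-hold tremor is attenuated and radially clipped at 0.7 of the
home radius (headroom for filter overshoot at clip transitions).

The two cohort profiles are documented constants chosen to qualitatively
match the described group behaviours, not fits to any patient data: the
low-FoF-like profile reaches fast and accurately (80 mm/s, 2 mm endpoint sd,
0.6 mm tremor, 97% hit probability, larger excursion ranges), the
high-FoF-like profile is slow, noisy and unsuccessful (30 mm/s, 6 mm, 1.2 mm
tremor, 60% hit probability, reduced ranges — peripheral mobility shrinks
with fear). At the raised support heights both profiles stiffen (reach speed
×0.9/×0.8; the high-FoF hit probability additionally ×0.95/×0.85),
emulating postural threat. Calibration attempts vary by a 5% coefficient of
variation. `make_cohort()` draws FES-I scores uniformly within each group's
range (16–22 low, 23–64 high) and group-consistent clinical scores, and is a
pure function of its arguments and seed.

What passing tests on this simulator do and do not show: they verify the
*computational* pipeline end to end — geometry, dwell counting, reliability
arithmetic, model fitting, cutoff selection, cross-validation — under
behaviour that separates the groups cleanly (the default profiles yield AUC
≈ 1 at n = 19 + 19 — far cleaner than real cohorts behave).
They do not validate the clinical claim: real CoP data have postural drift,
non-stationary tremor, missed home holds, and overlapping group
distributions that no parameter here was fitted to reproduce.

## Problem sizes and numerics

The shipped test-and-acceptance configuration uses: 100 random trajectories
for the conservation/oracle sweep, n = 6000 samples for dwell-fraction
recovery (rounding bound 100/n ≈ 0.017 percentage points), 200 random
datasets up to n = 50 for the ROC/Youden brute-force equivalence, 20 small
datasets against a two-stage dense grid (±10 box, 0.005 final step) for the
logistic MLE, and one 19 + 19 cohort with three height levels and three
repetitions for the end-to-end run — sizes chosen so the whole suite
completes in well under a minute while every contract is exercised at its
stated tolerance. Seeds are explicit everywhere; every generator is
bit-reproducible given (parameters, seed), and RNG state is always restored
via an internal `local_seed()` so library calls never perturb a caller's
stream.

Known limitations: no artifact/spike removal or resampling (bad recordings
are rejected, not repaired); vendor raw formats are not parsed (export to
the documented CSV dialect); multivariable logistic models, calibration
curves and external validation are out of scope; and the simulator is a
point-mass caricature — useful as a harness, silent about physiology.
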