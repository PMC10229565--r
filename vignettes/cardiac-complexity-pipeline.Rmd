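---
title: "Cardiac complexity quantifiers and depressive-transition analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac complexity quantifiers and depressive-transition analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvtrans)
```

## The scientific problem

People who taper antidepressants after remission face a substantial risk of
depressive relapse, and there is no established physiological marker that
flags who is at risk. One candidate family of markers comes from the
complexity of cardiac dynamics: beat-to-beat (RR interval) series of healthy
hearts are neither metronomic nor random, and loss of that structured
variability accompanies many disease states. `hrvtrans` implements a
complete analysis pipeline for studies that record short (about 5-minute)
interbeat-interval (IBI) assessments twice daily over several months while
tracking weekly depressive-symptom scores: per-assessment complexity
quantifiers, clinically defined transition labels, within-subject
pre-transition trend tests, between-group baseline comparisons and
predictive models, and a surrogate-data check that the complexity values
reflect nonlinear dynamics rather than linear correlation.

Because raw recordings from such clinical cohorts are generally not
shareable, the package also ships a synthetic-cohort generator that
reproduces the statistical structure the analysis assumes, so every stage
is testable offline.

## The four quantifiers

Each usable assessment (at least 100 beats, at most 5% of intervals outside
300–2000 ms) is summarized by:

* **Mean IBI** (ms) — the average RR interval; inversely related to heart
  rate.
* **SDRR** (ms) — the standard deviation of RR intervals (sample, n − 1
  convention, the standard in HRV reporting).
* **Higuchi fractal dimension** — dimensionless, in [1, 2] for
  fractal-Brownian-like signals. For delay `k = 1..kmax` and offset
  `m = 1..k` the normalized curve length is
  `L_m(k) = [Σ |x(m+ik) − x(m+(i−1)k)| · (N−1)/(⌊(N−m)/k⌋ k)] / k`,
  `L(k)` is the mean over `m`, and `D` is minus the slope of `ln L(k)`
  against `ln k` (natural logs, unweighted least squares). We fix
  `kmax = 5`, appropriate for ~300–400-beat series where larger delays
  leave too few curve points.
* **Multiscale sample entropy (MSE)** — sample entropy
  `SampEn(m, r) = −ln(A/B)` (template length `m = 2`, Chebyshev distance,
  self-matches excluded, Richman–Moorman counting so a constant series
  gives exactly 0) computed on coarse-grained copies of the series (window
  means of width 1..5) and averaged over scales. The tolerance
  `r = 0.2 · SD` is fixed from the raw series and reused at every scale so
  that coarse-graining, which reduces variance, does not silently relax
  the matching criterion. The scale cap adapts so each coarse-grained
  series keeps at least `10(m+1)` points (5 scales for a typical 350-beat
  assessment).

The embedding length, tolerance fraction, scale rule and log base are not
uniquely pinned down by convention; they are exposed in
`complexity_config()` and echoed into run metadata so any analysis is
auditable. A consequence is that *absolute* MSE levels are
convention-dependent; contrasts, orderings and effect sizes are the
meaningful outputs.

Validation anchors (all recomputed by the test suite and
`scripts/acceptance.R`): a linear ramp has `D = 1`; white Gaussian noise
approaches `D = 2`; cumulated fractional Gaussian noise with Hurst
exponent `H` — an fBm track whose graph has fractal dimension `2 − H` —
recovers `D = 2 − H` within ±0.1 for `H ∈ {0.2, 0.5, 0.8}`. Note that the
`D = 2 − H` relation belongs to the *integrated* (fBm) path: stationary
fGn itself is dimension-2 roughness for every `H ≤ 0.5` (at `H = 0.5` it
*is* white noise), which is why the package validates the relation on
cumulative sums. Sample entropy is checked for exact equality against an
O(N²) brute-force template count.

## Transition labels

A subject is labeled as transitioning when their weekly SCL-90
depression-subscale score rises by at least 8.5 points above a reference
level and the elevation persists for at least three consecutive observed
weeks. The reference level is the mean of the first four available weekly
scores; the study design enrolls subjects in remission, so early weeks are
a meaningful baseline. Both the threshold and the persistence run are
configurable. Two deliberate conservatisms: missing weeks break a
persistence run (we never bridge gaps), and the clinical-override flag
(treatment change or tapering interruption, criterion established by
clinicians outside the data) is an input, never inferred. Non-transitioning
subjects receive *pseudo-transition* anchor weeks pair-matched from the
sorted transitioning subjects, capped at their last observed week, so that
window-based analyses treat both groups symmetrically.

Weeks are 0-indexed; week `w` covers study days `7w .. 7w+6`, day 0 being
the subject's first assessment day. The pre-transition window is the
half-open 8 weeks before the anchor week; the baseline window is days
0–27. Windows whose observed data span less than 3 weeks (21 days) are
flagged insufficient and excluded with a logged reason.

## Statistical machinery

* **Within-subject trends**: Kendall tau-b of each quantifier against
  `day_index` (not assessment ordinal, so missing days do not compress
  time), morning and evening series separately. Exact p for n ≤ 10 without
  ties, otherwise the tie-corrected normal approximation with continuity
  correction (the classical Mann–Kendall test). No multiplicity
  correction: the design reports per-test counts of significant trends at
  α = 0.05, and the null calibration of those counts is itself tested.
* **Between groups**: Mann–Whitney U (exact for both groups ≤ 8 without
  ties, tie-corrected normal approximation otherwise — both p-value styles
  agree within 0.02 in the 8–20 range), Cohen's d with pooled SD. The
  pooled-SD convention was verified by recomputing all eight published
  effect sizes from their printed group means and SDs (n = 14 per group):
  maximum absolute discrepancy 0.016, within printed-input rounding.
* **Prediction**: single-predictor logistic regressions of transition
  status on each baseline person-average. Predictors are standardized
  internally for IRLS stability and coefficients back-transformed to the
  raw scale; Nagelkerke R² and the share correctly classified at a 0.5
  fitted-probability cutoff are reported. Quasi-complete separation — a
  realistic outcome when an entropy predictor nearly splits 28 subjects —
  is diagnosed and reported (`converged = FALSE`) rather than crashed on.
* **Threshold discrimination**: a grid search over midpoints of adjacent
  sorted unique values, classifying the low side as "transition" (lower
  entropy ⇒ transition), ties broken toward the lowest threshold.
* **Nonlinearity**: IAAFT surrogates preserve the amplitude multiset
  exactly (the returned iterate is the rank-remapped one, the right choice
  when the downstream quantifier is amplitude-sensitive) and the Fourier
  spectrum approximately. The default comparison pools surrogate
  quantifier values across assessments into a two-sided Wilcoxon rank-sum
  test against the observed values; a per-assessment rank mode with an
  exact convolution null is available (`mode = "rank"`) and is preferable
  when assessments are strongly heterogeneous. Both modes hold their size
  on linear Gaussian AR(1) data; the validation suite measures the
  rejection rate over 200 replicates against the α = 0.05 ± 0.03 band.

## The synthetic cohort generator

`cohort_spec()` encodes the study conditions: 14 transitioning and 14
non-transitioning subjects, 120 days, two sessions per day, ~350 ± 40
beats per assessment, 10% of assessments missing completely at random,
transition weeks uniform on weeks 5–14, weekly symptom noise SD 2 points
and a sustained +10-point step at transition (a step, not a ramp, keeps
label recovery unambiguous; the threshold criterion is 8.5).

Each assessment is target mean + scaled mixture of a predictable
respiratory-like oscillation (a ~6.5-beat-period sinusoid plus a faster
harmonic) and a cumulated-fGn track. The per-subject `complexity_level`
shifts weight from the oscillation to the track and simultaneously
roughens the track, so multiscale entropy increases monotonically with it.
The harmonic share (`fast_fraction`) adds small-scale roughness that
raises the Higuchi dimension while remaining perfectly predictable; giving
the transition group a larger share reproduces the empirically observed
coupling of *higher* dimension with *lower* entropy. A single
roughness knob cannot produce that coupling at physiological dimension
levels (~1.6–1.7), which is why the generator separates the two. Mean-IBI
and SDRR targets per group and session are drawn from Gaussian
between-subject distributions matching the published person-averaged
M ± SD; realized assessment means and SDs hit their targets exactly by
construction. The complexity separation (0.30 vs 0.46, between-subject SD
0.07) was calibrated once so the person-averaged baseline MSE contrast
realizes Cohen's d ≈ −2, the magnitude the validation suite requires the
pipeline to recover.

Reproducibility is structural: every random draw is keyed by a stable
string hash of (master seed, subject, day, session), so adding a subject
or restricting the generated days/sessions never reshuffles any other
assessment, and the ground-truth table suffices to recompute every label.

What the generator does *not* emulate: ectopic beats and measurement
artifacts (the quality filter is exercised with synthetic corruption in
unit tests instead), circadian mean differences beyond the
session-specific targets, symptom ramps (available as a stress mode is
not; the step is the default shape), and any physiological feedback
between symptoms and cardiac dynamics. Passing the recovery suites
therefore demonstrates that the *pipeline* is correct and well calibrated
under its own assumptions — not that real tapering cohorts satisfy those
assumptions.

## Problem sizes and numerical choices

The validation suite and `scripts/acceptance.R` use the cohort sizes of
the study design (14 + 14)
with quantifiers computed on the baseline window of the morning session —
the arm of the analysis the recovery claims concern — across 100 replicate
cohorts (60 for the null-calibration arm), 200 replicates for the
surrogate-test size, and 50 series per Higuchi anchor. These sizes keep the
whole suite comfortably reproducible on a laptop while leaving binomial
noise well inside the asserted tolerance bands.

Numerical edge cases are flags, not crashes: constant series (zero curve
lengths make the Higuchi log–log fit degenerate → `NA` with a reason;
entropy 0 by the counting convention; IAAFT returns the input unchanged
since phases are undefined), entropy with no template matches (`Inf`
sentinel or `NA` with a reason, non-finite scales excluded from the MSE
mean and flagged), and separation in the logistic fit. Seconds-valued IBI
files are rejected with a conversion message rather than auto-converted.

## Known limitations

* The transition detector's exact-week recovery degrades quickly when the
  weekly symptom noise SD approaches the detection margin (the 8.5-point
  threshold leaves only 1.5 points of slack under the default +10-point
  step); at noise SD 2 roughly half of transitioning subjects are dated to
  a neighbouring week even though most are detected. Designs expecting
  sharper dating need either a larger step contrast or lower-noise symptom
  instruments.
* Absolute MSE levels depend on (m, r, scale) conventions and are not
  comparable across packages without matching configurations.
* The pipeline starts from clean IBI series; R-peak detection and ectopy
  correction are upstream concerns.
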