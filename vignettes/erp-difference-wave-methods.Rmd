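---
title: "Prefrontal oddball ERP difference-wave measurement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prefrontal oddball ERP difference-wave measurement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpmci)
```

## The problem

Mild cognitive impairment (MCI) is the transitional stage between normal
cognitive aging and dementia. Portable, low-density EEG devices make it
practical to record event-related potentials (ERPs) outside the laboratory:
two prefrontal electrodes (Fp1, Fp2) at 250 Hz during a five-minute active
auditory oddball task, in which 64 rare 2,000 Hz target tones are embedded
among 256 frequent 750 Hz standards and the participant presses a key on each
target. The P300 — a positive deflection 300–600 ms after a task-relevant
rare stimulus — indexes attention allocation and working-memory updating, and
its timing and shape are candidate markers of early cognitive decline.

This package implements, as a tested pipeline, the *differential-ERP*
measurement of that P300 together with the task's behavioral measures and the
group statistics used to compare a cognitively normal (CN) arm with an MCI
arm: pooled t-tests, a chi-squared test for sex, three nested logistic
regression models per feature, and covariate-adjusted Pearson partial
correlations against neuropsychological scores (MMSE and the five domain
scores of the Seoul Neuropsychological Screening Battery). Because the
underlying clinical recordings are not publicly deposited, the package also
contains a first-class synthetic-data generator that emulates the recording
and the cohort's statistical structure, so every downstream stage is testable
without any download.

## The measurement model

For each subject the two channels are averaged, presses are attributed to
stimuli (a press belongs to the most recent stimulus preceding it by a
latency inside [100, 1000] ms; a stimulus takes at most one press, the first
wins; unattributable presses are counted as stray), and trials are
classified: targets become hits or omissions, standards commissions or
correct rejections. Only *correct* trials are analyzed: hits for the target
condition, correct rejections for the standard condition.

Epochs of [−200, 800) ms around each correct stimulus onset (250 samples at
4 ms; onset at 0-based index 50) are baseline-corrected by subtracting the
mean of the [−200, 0) ms window. The per-condition averages are smoothed with
a centered nine-tap moving average (reflection-padded ends), and the
difference wave is the smoothed target average minus the smoothed standard
average. From the difference wave the nine measures are:

* **AMP, LAT** — value and time of the global maximum inside the 300–600 ms
  window (no prominence rule: the window maximum stands in for the expert's
  visual peak selection; a non-positive maximum invalidates the subject);
* **T1, T2** — the nearest sign changes of the difference wave at/before and
  after the peak, searched over the whole epoch (T1 routinely precedes
  300 ms), with crossing times linearly interpolated between samples; an
  exactly-zero sample is itself the crossing (ties resolved toward the peak);
  a missing crossing invalidates the subject — this is the algorithmic form
  of the "no discernible peak" exclusion;
* **AUC** — the trapezoidal integral of the difference wave over [T1, T2] in
  µV·ms, with interpolated partial end intervals; a non-positive area
  invalidates the subject (between bracketing crossings of a positive peak
  the signed and positive-part integrals coincide, which is why the signed
  integral is used);
* **FAL** — the 50% fractional-area latency: the time at which the cumulative
  area from T1 reaches AUC/2. Within a sample interval the piecewise-linear
  wave makes the cumulative area quadratic in time, so the half-area crossing
  is solved exactly rather than interpolated linearly; this is what lets
  closed-form waveforms (triangles, rectangles) be reproduced to 10⁻⁶;
* **T2T1 = T2 − T1, FALT1 = FAL − T1, T2FAL = T2 − FAL** — exact
  subtractions, so the additivity T2T1 = FALT1 + T2FAL holds to machine
  precision for every valid subject.

Two decisions here were genuinely open. First, whether the nine-tap smoother
runs before or after the difference is formed: it is applied to the two
averaged condition traces ("final ERP traces") before subtraction; since the
operation is linear the difference of smoothed traces equals the smoothed
difference, so the choice is presentational. Second, "order nine" is read as
nine taps, centered; a ten-tap or causal variant is configurable via
`erp_options()` but not default.

The six behavioral measures are: NI (commission count), ER = (commissions +
omissions) / hits, ACC = 100 · hits / targets, WER = ½ (commissions/standards
+ omissions/targets), RT (mean hit latency) and RTSD (sample SD of hit
latencies). The exact published formula sheet for ER/ACC/WER is not
available; these reconstructions are the ones consistent with the reference
cohort's printed group means — e.g. the CN-calibrated rates (≈1.52
commissions, 98.8% hits) give WER ≈ 0.009 and ER ≈ 0.036, matching the
printed 0.01 and 0.04, and ER's denominator can only be hits (any larger
denominator makes the printed value impossible). A subject with zero hits
has an undefined ER and is excluded, as are subjects with ER above 1
("extreme errors").

## The statistical battery

Group comparisons use the pooled-variance (Student) t with df = n₁ + n₂ − 2,
computable either from raw per-subject values or directly from printed group
means/SDs — the summary form is what makes the reference tables recomputable.
The sign convention is t = (CN − MCI)/SE. Sex uses Pearson's chi-squared
without continuity correction (the uncorrected statistic reproduces the
printed 0.217). Logistic models of MCI status are fitted by maximum
likelihood (`glm`, log-likelihood tolerance 10⁻⁸, ≤100 iterations) in three
nestings: the feature alone; plus age, sex (female = 0, male = 1) and years
of education; plus MMSE. Predictors are z-scored over the analysis sample
before fitting, so odds ratios are per SD: the reference ORs (e.g. 1.27 for
AUC, whose SD is ≈290 µV·ms) are impossible per raw unit and natural per SD,
so the per-unit phrasing in the source narrative is treated as imprecise.
`fit_logistic(..., standardize = FALSE)` gives the per-unit scaling. Partial
correlations residualize both variables on the covariates (plus intercept) by
least squares and correlate the residuals, with p from
t = r √((n − 2 − k)/(1 − r²)). All tests are two-sided at a single α = 0.05
with no multiplicity correction, and significance is reported with the
``***``/``**``/``*``/`ns` star convention.

## What the generator emulates

Each synthetic session is: per channel, pink (1/f) noise scaled to
`noise_sd_uv` plus a 10 Hz alpha oscillation of amplitude `alpha_power` with
random phase, plus an evoked response shared by both channels — a negative
Gaussian N100 bump after every stimulus and a positive Gaussian P300 bump
(amplitude, latency, width per subject) after every target. Presses follow
per-trial Bernoulli hit/commission draws with ex-Gaussian latencies. Stimulus
sequences place targets uniformly among arrangements with no two consecutive
targets; inter-stimulus onsets are uniform on [900, 1100] ms (the source
states 320 stimuli in five minutes but no ISI; 1000 ms nominal leaves margin
and is configurable, as are the stimulus-duration and response-window values,
none of which are published).

Subject-level parameters are drawn from truncated normals whose *location is
solved so the truncated mean equals the configured target*. This matters for
parameters whose target sits within a couple of SDs of a bound (a hit rate of
0.988 ± 0.022 against 1): naive truncation would shift the realized mean by
far more than sampling error, and the generator's contract is that for ≥1,000
subjects per group every parameter's sample mean lies within 3 SE of its
configured value. Demographic and neuropsychological scores use the reference
cohort's group means/SDs directly; correlations between scores default to
zero because the generative dependence structure is unpublished.

Evoked-component defaults were calibrated once against the reference feature
means: amplitudes 6.58/7.99 µV and latencies 388/393 ms map one-to-one;
widths (34 ms CN, 42 ms MCI, given 8 µV-SD background noise) were set so the
measured component duration T2T1 lands near the published 238/285 ms, since
the crossings arise where the component tail sinks into the averaged noise
floor. About 12% of default-calibration subjects fail the crossing gate,
echoing the reference study's own heavy "no discernible peak" exclusion.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: eye-blink/EMG artifacts and drowsiness, skewed
(non-Gaussian) component shapes (the published FALT1 > T2FAL asymmetry cannot
arise from a symmetric bump; our measured halves come out nearly equal), the
published AUC magnitude (the printed mean of ≈246 µV·ms is mutually
inconsistent with the printed amplitude and duration for any single-lobed
positive component, so AUC is left emergent and only its group direction is
meaningful in simulation), any correlation between neuropsychological scores
and ERP physiology beyond what the group labels induce, and resting-state or
sensory-evoked recording conditions.

## Numerical and reproducibility choices

All randomness flows from integer seeds through `withr::with_seed`, so the
caller's RNG state is never disturbed. A cohort's master seed spawns a
per-subject triple (parameters, stimulus sequence, session) by sequential
draws, so subject *i* is unchanged when a cohort is extended. Pink noise is
synthesized spectrally at the next 2-3-5-smooth FFT length and truncated.
Event times are carried at millisecond precision to three decimals so the
text session format round-trips events exactly; samples round-trip far below
the 16-bit quantization of clinical EEG storage. Degenerate inputs have
defined behavior: zero pooled variance yields t = 0 (equal means) or an
infinite-t flag; constant logistic predictors, rank-deficient designs and
(quasi-)separation raise diagnostic errors, and a degenerate feature voids
only its own rows of the model table; a variable fully explained by the
covariates has partial correlation exactly 0; constant covariates are dropped
from the correlation adjustment.

## Problem sizes used by the checks

The automated checks run at sizes chosen to finish in minutes on one CPU
while keeping their statistical claims meaningful: calibration fidelity at
1,000 subjects per group (parameter level, no signal synthesis); P300
parameter recovery at 200 full sessions with per-subject amplitude/latency/
width variation and light-to-moderate noise, asserting cohort means within
3 SE — the 9-tap smoother attenuates a 50 ms-wide Gaussian peak by ≈2%, which
is why recovery is asserted statistically rather than exactly; engine
properties at 500 replicates (Wald coverage, n = 334), 2,000 replicates
(pooled-t type-I error at n = 239/95) and n = 5,000 (odds-ratio recovery).
The full-cohort structure check runs at the reference sizes 239/95. The
group-direction check runs on an equal-arm cohort of 600 per group: at
239/95 the weakest significant reference effect (T1, printed t = 2.38)
corresponds to a simulated mean difference of ≈18 ms against a ≈90 ms SD,
where the sign of the sample contrast is itself noisy; at 600/600 every
significant feature reproduces its direction with |t| between about 2.7 and
16. Directions are asserted only for features the reference reports as
significant — for rows with printed |t| ≤ 1.65 the printed sign is itself
sampling noise and asserting it would be asserting a coin toss.

## Known limitations

The subject-level reference results (the printed odds ratios and the
correlation heat-map values) depend on the private recordings and are not
reproducible from summaries; they are covered only by the direction and
structure checks described above. The generator's Gaussian component cannot
express component skew; its AUC scale is internally consistent but not
matched to the printed AUC row; and ER's printed summaries (0.04/0.05 and
0.09/0.12) are too coarsely rounded to pin its t statistic, which is why the
ER row is exempt from the printed-t recomputation tolerance.
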