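# erpmci

Prefrontal oddball ERP difference-wave features and group statistics for
studying mild cognitive impairment (MCI).

Clinical screening for MCI increasingly uses portable two-channel prefrontal
EEG (Fp1/Fp2, 250 Hz) with an active auditory oddball task: 64 rare 2,000 Hz
target tones among 256 frequent 750 Hz standards, key-press on targets. This
package is a tested implementation of that analysis for a two-group cohort
(cognitively normal, CN, vs. MCI):

* **Synthetic cohorts** — seeded, calibrated simulation of full sessions
  (pink-noise + alpha background, Gaussian N100/P300 evoked components,
  Bernoulli/ex-Gaussian behavior) plus demographics and neuropsychological
  scores, so the whole pipeline runs with no external data.
* **ERP measurement** — the differential-ERP method. With
  \(d(t)\) the smoothed target-average minus standard-average difference
  wave over correct trials (epochs \([-200, 800)\) ms, baseline
  \([-200, 0)\) ms, nine-tap moving average):
  AMP and LAT are the peak value/time of \(d\) in 300–600 ms; T1 and T2 the
  interpolated zero crossings bracketing the peak;
  \(\mathrm{AUC} = \int_{T1}^{T2} d(t)\,dt\) (µV·ms); FAL solves
  \(\int_{T1}^{\mathrm{FAL}} d = \mathrm{AUC}/2\); and
  T2T1 = T2 − T1, FALT1 = FAL − T1, T2FAL = T2 − FAL. Subjects without a
  positive peak or a pair of crossings are excluded ("no discernible peak").
* **Behavioral measures** — NI (commissions), ER = (NI + omissions)/hits,
  ACC = 100·hits/targets, WER = ½(NI/standards + omissions/targets), RT,
  RTSD.
* **Statistics** — pooled-variance Student t (from raw data *or* printed
  group summaries), chi-squared (no continuity correction), three nested
  logistic models per feature (unadjusted; + age/sex/education; + MMSE;
  per-SD odds ratios with Wald 95% CIs), and Pearson partial correlations
  adjusted for age, sex and education.

## Worked example

The `analysis/` scripts run the full study in order:

```sh
Rscript analysis/01_simulate_cohort.R    # 239 CN + 95 MCI subjects
Rscript analysis/02_extract_features.R   # measure every subject, exclusions
Rscript analysis/03_group_statistics.R   # t-tests, logistic models, correlations
Rscript analysis/04_reference_checks.R   # recompute the published t statistics
```

On the default configuration (`seed = 42`) this prints, among other things:

```
Measured 334 subjects; 303 included.
Exclusions: no_target_responses = 0, extreme_errors = 0, no_discernible_peak = 31
Cohort means: AMP 6.54 uV, LAT 391.3 ms, T2T1 268.5 ms

Features still associated with MCI after full adjustment (model 3):
   variable odds_ratio ci_low ci_high        p
21    FALT1      1.503  1.155   1.955 2.42e-03
27     T2T1      1.376  1.054   1.796 1.90e-02
...
```

i.e. 31 simulated subjects fail the discernible-peak gate, and the P300
duration measures remain associated with MCI after adjusting for
demographics and MMSE — the qualitative pattern the method is designed to
expose. `04_reference_checks.R` recomputes the pooled t statistics from the
bundled published group summaries (n = 239/95); every recomputable row
agrees with the printed value to ≤1.7% (ER/WER's printed summaries are too
coarsely rounded to pin their t):

```
   variable t_printed t_recomputed   rel_err
3      MMSE      6.19        6.181 -1.77e-03
13       T1      2.38        2.377 -1.19e-03
17     T2T1     -3.30       -3.300  1.49e-04
```

In code, the same machinery is three calls:

```r
library(erpmci)
res <- run_pipeline(pipeline_config(seed = 42))
res$ledger                      # exclusion accounting
res$tables$features             # 15-feature group comparison
res$tables$logistic             # 15 x 3 nested odds ratios
```

## Layout

* `R/` — the package: simulation (`generate_stimulus_sequence`,
  `simulate_subject_params`, `synthesize_session`, `generate_cohort`),
  measurement (`extract_erp_features`, `compute_behavioral`), statistics
  (`students_t_from_summary`, `fit_logistic`, `nested_models`,
  `partial_correlation`, `build_comparison_tables`), and I/O
  (`write_session`/`read_session` text dialect, YAML configs, reports).
* `inst/extdata/` — the reference cohort's published group summary
  statistics (inputs to the recomputation).
* `vignettes/erp-difference-wave-methods.Rmd` — the methods account: model
  assumptions, calibration, numerical choices, limitations.
* `tests/testthat/` — unit, property and acceptance tests.
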