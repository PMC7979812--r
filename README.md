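# readscan

Reading eye-movement profiling for multi-line paragraph reading: from raw
fixation/saccade/blink event streams to a full two-group eye-movement
profile — cleaning, word-based interest mapping, global and local reading
metrics, a saccade taxonomy that isolates reading-atypical *directional
deviations*, duration-weighted scanpath similarity with clustering, and a
statistics layer built on unbiased effect sizes.

## Who this is for

Researchers in visual psychophysics and reading who record eye movements
during naturalistic paragraph reading (e.g. with a video-based tracker and
DataViewer-style event reports) and want a reproducible, scriptable version
of the standard analysis stack used to compare reader groups — for example
adult readers with and without dyslexia.

## What it computes

For each cleaned trial, fixations are assigned to padded word interest
areas and the pipeline derives:

* **Global metrics** — mean/median fixation duration, saccade-amplitude
  central tendencies, total scan path (sum of amplitudes in degrees of
  visual angle), reading speed in words/minute.
* **Local metrics** — first-pass segmentation behind an advancing frontier:
  first-run dwell time (gaze duration summed over words), first-pass skip
  ratio, ratio of visited words, fixations per word, number and probability
  of regressions.
* **Saccade taxonomy** — return-sweeps (last 3 words of a line to first 3 of
  the next), undersweeps (launched from the last 4 words, landing mid-line,
  followed by a leftward corrective), line-initial fixations (first fixation
  on a line's first two words without a leftward corrective), and
  **directional deviations**: saccades with angles between ±35° and ±145°
  off the reading axis after excluding blinks, sweeps and undersweeps —
  markers of a momentary loss of place.
* **Scanpath similarity** — the Scasim alignment: gap cost = fixation
  duration, substitution cost
  `dur_a + dur_b − 2·min(dur_a, dur_b)·m^d(a,b)` with `d` the angular
  distance in degrees and `m = 0.83` per degree; scores normalized by the
  two trials' summed fixation durations, embedded by non-metric MDS,
  clustered with a GMM-BIC-selected k, and tested for cluster-group
  association (χ²/Fisher).
* **Group statistics** — unbiased Hedges' g
  (`g = J·(m₁−m₂)/s_pooled`, `J = 1 − 3/(4df−1)`) with *exact* 95% CIs from
  inverting the noncentral-t distribution; pooled t-tests; JZS Bayes
  factors (Cauchy width 0.7); percentage-bend correlations (20% bending);
  Bonferroni-corrected chance tests; gamma-GLMM design construction with
  deviation coding and likelihood-ratio comparisons.

A synthetic scanpath generator (`simulate_trial()`, `simulate_cohort()`)
produces two-group cohorts whose defaults encode published group reading
signatures (fixation medians 202 vs 224 ms, line-initial 216 vs 256 ms,
deviation rates 0.44 vs 1.00 per trial with opposite modal directions), so
the entire pipeline can be exercised without any proprietary stimuli or
downloads.

## Worked example

Effect size from published summary statistics (WAIS Coding processing
speed; control 12.84 ± 2.53, n = 32 vs dyslexia 9.40 ± 2.27, n = 35):

```r
library(readscan)
hedges_g(12.84, 2.53, 32, 9.40, 2.27, 35)
#> Hedges' g = 1.418, 95% CI [0.892, 1.969] (n1 = 32, n2 = 35)
#> sign convention: negative = dyslexia larger/longer
```

A positive g means the control group scores higher; the CI excluding zero
marks the group difference significant under the effect-size criterion.

End-to-end on a small simulated cohort (5 + 5 participants, 3 texts):

```r
spec <- cohort_spec(5, 5, 3, master_seed = 7)
res <- run_pipeline(spec, seed = 7)
res$effect_sizes[, 1:4]
#>                           metric       g  ci_lo  ci_hi
#> 1                  median_fixdur -2.9446 -4.079 -1.949
#> 2                 total_scanpath -0.5800 -1.323  0.141
#> 3                median_sacc_amp  3.0276  2.018  4.181
#> 4                    sd_sacc_amp  1.2794  0.512  2.099
#> 5           first_run_dwell_time -3.3544 -4.584 -2.287
#> 6  ratio_first_run_words_skipped  2.2930  1.401  3.287
#> 7            ratio_visited_words -4.0173 -5.409 -2.825
#> 8             fixations_per_word -3.3394 -4.565 -2.274
#> 9                  n_regressions -0.8361 -1.602 -0.102
#> 10        regression_probability  0.0253 -0.690  0.742
#> 11    median_line_initial_fixdur -1.2636 -2.081 -0.498
#> 12      n_directional_deviations -0.9641 -1.744 -0.222
```

The dyslexia-profile group shows longer fixations, longer first-run dwell,
more regressions and more directional deviations (negative g), larger
saccades and more skipping in the control group (positive g), and — by
construction of an equal per-saccade regression hazard — no difference in
regression *probability* (CI includes zero). Per text-font pair, scanpath
clustering and cluster-group association:

```r
res$similarity
#>   text font  n k method       p
#> 1  t01  TNR 10 3 fisher 0.04762
#> 2  t02   OD 10 3 fisher 0.00794
#> 3  t03  TNR 10 2 fisher 0.44444
```

Event streams can be written/read as plain TSV event reports
(`write_event_report()` / `read_event_report()`) for interoperability with
external preprocessing.

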