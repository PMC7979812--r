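---
title: "Profiling reading eye movements: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling reading eye movements: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readscan)
```

## The problem

During reading, the eyes alternate between fixations (stops of roughly
200-250 ms during which text is encoded) and saccades (fast jumps of 7-9
characters). Adult readers with dyslexia show a characteristic signature on
these events: longer fixations, shorter saccades, fewer skipped words, more
regressions, and — more rarely quantified — saccades whose direction is
atypical for the left-to-right reading flow altogether. `readscan`
implements a complete analysis pipeline for multi-line paragraph reading
that computes this profile from per-trial fixation/saccade/blink event
streams: event cleaning, word-based interest mapping, global (trial-level)
and local (word-level) metrics, a saccade taxonomy, duration-weighted
scanpath similarity with clustering, and a group-comparison layer built on
unbiased effect sizes.

Because the standardized paragraph stimuli used in reading-speed assessment
are commercial and their raw recordings are not bundled here, the package
ships a synthetic scanpath generator whose defaults encode the published
group-level reading signatures. Every stage of the pipeline is exercised
end-to-end against that generator's known ground truth.

## Event cleaning

Cleaning follows the standard reading-analysis recipe, with thresholds in
`cleaning_config()`:

* **Interest period** (`interest_trim_ms = 300`): the first and last 300 ms
  of each trial are discarded; fixations straddling a cutoff are clipped and
  their duration recomputed. Trials shorter than twice the trim are flagged
  and excluded.
* **Blink-adjacent removal** (`blink_adj_ms = 50`): fixations immediately
  before and after a blink are removed, and fixations separated by a blink
  are never merged. "Immediately" is operationalized as a 50 ms window
  between the fixation edge and the blink edge. A pure
  nearest-in-the-event-stream rule is not idempotent — run twice, it would
  strip the next-nearest fixations as well — whereas the windowed rule is,
  and in event streams recorded by video eye trackers the flanking
  fixations sit only a few milliseconds from the blink.
* **Merging** (`merge_amp_deg = 1`): consecutive fixations closer than one
  degree are merged pairwise, left to right, durations summed and the
  position set to the duration-weighted mean. Merging runs *before* the
  duration filter so that short refixation fragments survive as merged
  fixations; the order of rules is visible in the code and configurable
  thresholds make it auditable. Merging is pairwise-sequential (each merged
  fixation is immediately compared with the next candidate), which makes a
  second cleaning pass a no-op.
* **Duration filter** (`min_fix_ms = 50`) and **bounds filter** (fixations
  beyond the display are dropped).
* **Saccade re-derivation** (`min_sacc_amp_deg = 0.5`): because removals
  invalidate recorded fixation-saccade pairings, saccades are rebuilt
  between consecutive retained fixations; displacements under half a degree
  produce no saccade. A saccade spanning a blink carries a flag.

Pixel-to-degree conversion uses the full `2 atan(d px / 2D)` formula with
the display geometry (default: 1024 x 768, 0.4 mm pixels, 70 cm viewing
distance, giving ~30.5 px per degree).

## Interest mapping

One interest area per word: the word box padded by 5 px on all sides,
vertical extents unified per line, and residual horizontal gaps between
neighbours split at the midpoint so every line is tiled without holes
(shared boundaries belong to the left/upper area). The original analyses
filled gaps with a renderer-internal background-colour heuristic; geometric
midpoint splitting is the portable equivalent.

Vertical drift correction (`correct_vertical_drift()`, off by default)
replaces manual per-trial adjustment with a deterministic optimizer: integer
vertical shifts within half a line spacing are scored by a
centrality-weighted in-area count (weight 1 at a line band's vertical
centre, falling linearly to 0 at its edge) and the best shift is applied to
all fixations at once — never per fixation, never horizontally. A raw
in-area count was rejected as the objective because it is piecewise constant
in the shift: any offset smaller than the band half-height ties with zero,
and a shift that happens to drag a stray between-line fixation into the
neighbouring band can even beat the true alignment. The triangular weight
makes the optimum unique; an injected uniform offset is recovered exactly.

## Metrics

First-pass segmentation walks the assigned fixations behind an advancing
frontier (the largest word index reached). A word's *first run* is its
maximal consecutive block of fixations on first arrival; a word is *skipped*
when the frontier passes it before any fixation lands on it, and later
fixations on it remain revisits. From the segmentation come first-run dwell
time, the first-pass skip ratio, the ratio of ever-visited words and
fixations per word; from the cleaned events come fixation-duration and
saccade-amplitude central tendencies, the total scan path (sum of amplitudes
in degrees) and reading speed in words per minute. Two denominator choices
are deliberate and configurable in concept: fixations-per-word divides by
*all* words of the text (keeping it independent of the visited-words ratio),
and words-per-minute uses the *untrimmed* trial duration, because reading
speed is a behavioural quantity measured from text onset to the reader's
key press, before any event trimming. Unassigned fixations count toward
duration statistics but not toward word-based metrics.

## Saccade taxonomy

Angles follow the reading convention: 0 degrees is rightward along the text,
positive is upward, computed as `atan2(-dy, dx)` because screen y grows
downward. Categories are assigned with the precedence blink-adjacent >
return-sweep > undersweep > directional deviation > regression > forward:

* **return-sweep**: launched from one of the last three words of a line,
  landing on one of the first three words of the next;
* **undersweep**: launched from one of the last four words, landing on the
  next line beyond its first three words, *and followed by a leftward
  corrective saccade within that line*. The launch-site rule alone would
  double-label every accurate sweep; the corrective clause is what makes an
  undersweep an undersweep, and it is the same saccade that disqualifies a
  line-initial fixation;
* **directional deviation**: |angle| between 35 and 145 degrees
  (inclusive at both bounds, configurable), provided none of the above
  exclusions fired and no blink occurs immediately before, during or after
  the saccade ("immediately" = in the adjacent inter-fixation gaps, with no
  intervening fixation);
* **regression**: leftward in word order to a previously visited or skipped
  word;
* everything else is forward (or other, for unassignable cases such as
  zero displacement).

Line-initial fixations are, per line, the temporally first fixation on one
of its first two words, unless the next saccade moves leftward of it within
the same line. The first line's first fixation also qualifies (it equally
lacks parafoveal preview). If the candidate is disqualified, the line
contributes none: the rule keys on the *very first* landing, not the first
valid one. Deviation angles are binned at 2.75 degrees over the two
qualifying bands (40 bins per half-plane), so the counts sum exactly to the
number of deviations.

## Scanpath similarity and clustering

`scasim_pair()` aligns two fixation sequences by dynamic programming:
deleting or inserting a fixation costs its duration, and substituting
fixations a and b costs `dur_a + dur_b - 2 min(dur_a, dur_b) m^d(a,b)`,
where d is the angular distance between the two positions in degrees and
the modulator m (default 0.83 per degree) controls how quickly spatially
mismatched time loses credit. Identical scanpaths cost 0; a scanpath
against an empty one costs its total duration. The core is implemented in
C++; an exhaustive alignment enumeration serves as its oracle in the tests.

Scores are computed per text-font pair (the analysis is coordinate-based,
so fonts with different spacing are never mixed) and normalized by the
summed total fixation duration of the two trials. The sum was chosen as the
denominator because it bounds the raw score, making the normalized value a
[0, 1] fraction interpretable as the proportion of viewing time spent
dissimilarly; mean or max normalization would only rescale it.

Clustering mirrors the dist -> non-metric MDS -> Gaussian-mixture BIC ->
k-means sequence: Euclidean re-distancing of the dissimilarity matrix rows,
`MASS::isoMDS` to two dimensions, `mclust::mclustBIC` over k = 1..9 to pick
the component count, then `stats::kmeans` with 50 restarts under a fixed
seed. The double distancing (Euclidean distances between rows of a matrix
that is already a dissimilarity) is faithful to the stated sequence and kept
as the default; `direct = TRUE` scales the dissimilarities themselves. One
behaviour worth knowing: non-metric scaling preserves only the rank order of
dissimilarities, so an idealized two-point-mass structure gets its
within-cluster spread compressed toward zero and BIC may refine each mass
into several coincident micro-clusters. The component search is therefore
capped at a third of the trial count (clusters keep at least ~3 trials on
average), and cluster-group association (the scientific question) is
unaffected either way — the clusters remain group-pure — and on
realistic matrices with continuous spread the selected k falls in the 2-5
range. Association is tested on the k x 2 contingency table with a
chi-square test when all expected counts are at least 5 and Fisher's exact
test otherwise.

## Group statistics

Effect sizes are unbiased Hedges' g: `g = J (m1 - m2) / s_pooled` with
`J = 1 - 3/(4 df - 1)`, sample 1 the control group, so metrics on which the
dyslexia group is larger or longer carry a negative sign. The 95% CI is the
*exact analytical* interval obtained by inverting the noncentral t
distribution in its noncentrality parameter (bisection to 1e-8) and
rescaling by `sqrt(1/n1 + 1/n2)`; following the convention of the standard
effect-size toolboxes, the bias correction J scales the point estimate but
not the CI bounds. JZS Bayes factors integrate the Cauchy-prior (width 0.7
by default) marginal likelihood of the t statistic with adaptive
quadrature. The percentage-bend correlation winsorizes 20% of standardized
deviations per variable around the percentage-bend measure of location
before correlating the clipped scores. The reading-duration GLMM is
represented by its design — mean-centred deviation codes for group, font
and their interaction, and a maximal no-correlation random-effects
structure (by-participant intercept + font slope; by-text intercept +
group, font and interaction slopes) — with fitting delegated to
`lme4::glmer` (gamma family, identity link, bobyqa) behind
`fit_reading_glmm()`; the package's own contribution there is the coding,
the collinearity check and the likelihood-ratio comparison `lrt()`.

## The synthetic generator

`simulate_trial()` walks a generated layout word by word: skipping with a
length-dependent probability, refixations landing at the far end of long
words, same-line regressions followed by a return to the launch word, a
return-sweep at each line end (undersweeps land mid-line and are corrected
leftward), lognormal fixation durations parameterized by their median (the
right skew of empirical duration distributions is why a lognormal, and
median-parameterization matches how group differences are reported), a
constant inflation on each line's first fixation, Poisson blinks, and
Poisson directional-deviation excursions. Group defaults
(`control_profile()`, `dyslexia_profile()`) encode the published group
signatures: fixation-duration medians 202 vs 224 ms, line-initial
inflations 14 vs 32 ms, deviation rates 0.441 vs 1.003 per trial with
upward vs downward modal directions, skipping 0.35 vs 0.15, refixation 0.15
vs 0.35, undersweep rates 0.15 vs 0.30, and a common per-fixation
regression hazard of 0.12.

Three generator choices deserve explanation:

* **Deviations are excursion-return pairs landing between lines.** The
  excursion drops 35 px (about 1.15 degrees — outside the 1-degree merging
  radius) from the word-box centre into the inter-line gap, where no
  interest area lives, and the walk resumes at the next sufficiently distant
  word so the return saccade stays below the 35-degree band. Because the
  excursion is never assigned to a word, the first-pass frontier, the skip
  bookkeeping and the regression count are untouched by an insertion: the
  taxonomy detects exactly the inserted deviations, and the per-trial
  deviation rate is recovered to within Monte-Carlo error. The default line
  spacing of 55 px exists to give that gap; it is wider than single-spaced
  text but within the range of double-spaced reading displays.
* **Regression hazard is per fixation, not per forward step.** With a
  per-fixation hazard q, the ratio of regressions to saccades is
  approximately q/(1+2q) in *both* groups regardless of their skipping and
  refixation rates, which is precisely the equal-hazard condition under
  which the regression *probability* should show no group difference even
  as the regression *count* does. This is the one metric the profile
  comparison is designed to leave null.
* **Saccade timing is schematic.** Inter-fixation gaps are 20 ms plus 2 ms
  per degree of amplitude — the right order of magnitude for reading
  saccades — and blinks extend their gap. No velocity profiles, no
  binocular disparity, no pupil dynamics.

What the generator does *not* emulate: linguistic content (word frequency
and predictability effects on skipping and durations), landing-position
distributions within words, calibration drift over time, or the
overdispersion of empirical deviation counts (the published variances
exceed Poisson; the generator is Poisson). Passing tests therefore
demonstrate that the pipeline measures what the generator encodes — rule
recovery, calibration, directional effects at realistic magnitudes — not
that real recordings would be reproduced in detail.

## Problem sizes and numerical choices

The simulation-based checks run a 10 + 10 participant cohort over 9 texts
in 2 fonts (360 trials), which reproduces the direction and significance
pattern of every profile metric in a few minutes on one core; the published
study's scale (32 + 35 participants) is reachable by changing
`cohort_spec()` only. Monte-Carlo calibrations use 2 000 replicates for CI
coverage and 5 000 for type-I rates. Exact-CI root finding brackets the
noncentrality parameter adaptively and tolerates 1e-8; the Bayes-factor
quadrature is checked against a fine Riemann sum to 1e-6 relative. Seeds
derive deterministically from a single master seed (kept below 2^31), so
cohorts, trials and clusterings are bit-reproducible.

## Known limitations

Event streams are the input level: the package does not parse vendor binary
files nor detect events from raw gaze samples. One eye per participant is
assumed. The undersweep definition requires an observed corrective saccade,
so an undersweep whose corrective was lost to cleaning is classified by its
angle instead. Whether a line's first fixation after a deviation excursion
should be eligible as line-initial is not specified by the field's rule; the
implementation keys only on word position and the corrective clause. The
exact normalization denominator and modulator used in the original
similarity analyses are not published; numeric equality with those matrices
is not claimed, only the qualitative clustering behaviour.
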