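---
title: "From gaze samples to diagnostic-region attention profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gaze samples to diagnostic-region attention profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facegaze)
```

## The problem

When observers categorize an emotional facial expression, their eyes do not
sample the face uniformly: each emotion has *diagnostic* regions (a frowning
brow for anger, a smiling mouth for happiness, a wrinkled nose for disgust)
that tend to attract fixations earlier and hold them longer. With *dynamic*
expressions — a face unfolding from neutral to emotional over about a second —
the question acquires a time axis: *when* during the unfolding does selective
attention to the diagnostic region emerge, and *for how long* does it persist?

`facegaze` implements the full analysis chain for this question: from raw
500-Hz gaze sample streams recorded over 1,033-ms expression clips, through
velocity-based event detection and region-of-interest (ROI) attribution, to
by-items attention norms, a binned gaze time course with its
threshold/amplitude summary, categorization confusion tables, and the
inferential statistics (by-items ANOVAs, Bonferroni contrasts, compact letter
displays) used to report them. Because raw recordings of this kind are rarely
deposited, the package also contains a seeded synthetic scanpath and response
generator with the statistical structure the analysis assumes, so every stage
is testable end to end.

## Event detection: the I-VT model

Gaze samples arrive as `(t, x, y, valid)` tuples at 2-ms spacing. Angular
speed at sample $i$ is the central difference

$$v_i = \frac{\|\,p_{i+1} - p_{i-1}\,\|_{\deg}}{t_{i+1} - t_{i-1}},$$

with one-sided differences at stream endpoints and undefined speed where a
required neighbor is invalid. Pixel positions are converted to degrees with
per-axis arctangent pixel pitch, so non-square pixels are handled. No
velocity smoothing is applied by default (`smooth_window` is available):
the velocity-threshold scheme is specified by only two constants, and we
prefer the reproducible bare algorithm over emulating any vendor's
unpublished filtering.

Samples with $v > 40$ deg/s form saccades; contiguous below-threshold runs
are fixation candidates; candidates shorter than 80 ms are discarded (the
80-ms boundary is inclusive). Maximal invalid runs of at least 75 ms are
blinks, shorter ones dropouts; the 75-ms figure is a conventional choice —
the distinction only affects labeling, since *all* invalid samples are
excluded from net gaze. *Net gaze* is the sample mask "inside a retained
fixation and valid"; saccades, blinks, dropouts and sub-minimum candidates
are all excluded. Every sample belongs to exactly one class, so fixation +
saccade + discarded + invalid time tiles the trial exactly — an identity the
test suite asserts on every simulated stream.

Two tie-break conventions worth knowing: event intervals are
`[onset, last sample + sampling interval)`, so durations are whole sample
counts and a fixation ongoing at clip offset is truncated there; and
fixations are *not* merged across brief intervening saccades (merge
parameters would be a separate, explicitly enabled step).

## Regions of interest and the four measures

Three ROIs — eye/eyebrow band, nose/cheek band, mouth band — are rectangles
parameterized as height fractions of the face bounding box (the default box
subtends 8.8° × 11.6° at 80 cm, centered on screen). The forehead and chin
are deliberately uncovered; points outside every ROI are `"other"`.
Membership is a closed-boundary point-in-polygon test; should regions ever
overlap, the fixed priority eyes > mouth > nose resolves it.

A fixation's ROI is decided by its *centroid* (per-sample attribution is
available for gaze durations, but centroid attribution keeps durations and
counts consistent). Four measures are computed per trial and then averaged
across observers for each stimulus ("by items"):

* **Probability of first fixation** — the ROI of the first fixation after
  the fixation carried over from the central cross. That carried-over
  fixation is identified *spatially* (leading fixations whose centroid lies
  within 1.0° of the cross position), not by its nose label: later nose
  landings are real first fixations, which is why nose first-fixation
  probabilities can be nonzero. Trials whose first fixation lands outside
  every ROI stay in the denominator, so the three probabilities need not sum
  to 1.
* **Probability (and time) of entry** — whether any retained, non-carried-over
  fixation lands in the ROI, and the onset of the earliest one. Entry times
  are averaged over entering trials only.
* **Gaze duration** — net-gaze milliseconds attributed to the ROI.
* **Number of fixations** — count of retained fixations by centroid ROI.

## Gaze time course, threshold and amplitude

Net gaze is binned into ten consecutive 100-ms intervals; the final 33 ms of
the 1,033-ms clip are discarded. The proportion for region $r$ in bin $k$ is
ROI net-gaze time divided by the *bin length* (100 ms), not by fixated time
in the bin — saccade and blink time then dilutes all regions equally and
proportions remain comparable across bins.

For a target expression and region, each bin is tested with a one-way
by-items ANOVA across expressions; in omnibus-significant bins, single-step
Bonferroni pairwise contrasts (pooled error term) decide whether the target
expression's mean exceeds, and differs significantly from, every expression
in a *comparison set*. The **threshold** is the earliest such bin; the
**amplitude** is the length of the consecutive run of advantage bins starting
there (a later isolated advantage bin is reported but not merged — the
summary describes one sustained episode of selective attention). When two
expressions jointly lead a region (anger and sadness on the eyes, in both the
published pattern and the generator defaults), neither can beat the other;
each co-leader's advantage is assessed against the comparison set excluding
the other.

## Inferential statistics

All analyses are by items: the stimulus (model × expression clip) is the
unit, with scores averaged across observers. `oneway_anova()` gives the
between-groups $F$, and `mixed_anova()` the split-plot decomposition for
expression (between items) × region (within items); both report partial eta
squared, $\eta_p^2 = SS_{\text{eff}} / (SS_{\text{eff}} + SS_{\text{err}})$,
each effect against its own error stratum. Degenerate all-constant input
yields $F = 0$ by definition rather than 0/0. No sphericity correction is
applied to the three-level within factor, matching the uncorrected degrees of
freedom such tables conventionally report.

Post-hoc contrasts are pooled-error t statistics with single-step Bonferroni
adjustment ($p_{\text{adj}} = \min(1, m\,p)$, $m$ = number of pairs; 15 for
six expressions). The exact statistic behind published superscript letters is
rarely stated; the pooled t following an omnibus ANOVA is the classical
choice and is declared here. `compact_letter_display()` renders contrast
matrices as letter codes via insert-and-absorb, with `"a"` attached to the
highest mean; the defining property — two groups share a letter iff their
contrast is non-significant — is verified exhaustively in the tests for every
display produced.

## The synthetic generator

`simulate_trial()` produces what the analysis consumes: a 517-sample stream
beginning at the cross position on the nose (gaze carries over from the
500-ms fixation cross), alternating log-normal fixation plateaus (median
250 ms, a typical empirical value) with constant-velocity saccade ramps at
300 deg/s — safely above the 40 deg/s threshold, while plateau positional
noise is a clipped random walk whose central-difference velocity stays well
below it. Saccade targets are drawn uniformly inside the ROI chosen from the
profile's dwell weights; the first post-center target uses a separate
first-target bias. A minimum saccade amplitude of 0.5° guarantees every
programmed saccade produces above-threshold samples. With configurable
probability (default 0.1) a trial contains one 75–150-ms blink of invalid
samples.

Default attention profiles encode the qualitative published pattern as
generator parameters: all expressions share a neutral, eyes-leaning weighting
until the fifth 100-ms segment — a face unfolding from neutral cannot drive
expression-specific gaze before it is discriminable — after which weights
become expression-specific (mouth-heavy happiness, eyes-heavy anger/sadness,
nose-heavy disgust, balanced surprise/fear), with ~3% of dwell outside the
three regions to match the ~97% coverage figure. At a weight-change boundary
an ongoing fixation is interrupted and a re-orienting saccade drawn under the
new weights; without this, event-level inertia (fixations in flight keep
stale targets) delays the *observed* dwell divergence by roughly one
fixation duration past the programmed segment. First-target biases are set
to the published first-fixation probabilities. Categorization responses are
multinomial draws from the packaged confusion-norm rows (renormalized to sum
exactly to 1), with log-normal hit RTs matching the published location and
scale per expression.

What the generator does *not* emulate — and therefore what passing tests do
not certify about real data: main-sequence saccade dynamics (amplitude–
velocity coupling), drift and calibration error, microsaccades, pupil
signals, smooth pursuit of the unfolding motion, head movement, or any
coupling between gaze pattern and the categorization response within a
trial. Parameter-recovery results show the pipeline is a consistent
estimator of the generator's attention structure, not that the published
values are correct.

## Numerical choices and degenerate inputs

* Clip timeline: total duration rounds to the nearest millisecond
  (31 frames at 30 fps → 1,033 ms); 517 samples at 2-ms spacing cover
  0–1,032 ms.
* Velocity at a valid sample flanked by an invalid one is undefined; such
  samples classify as fixation candidates (they are rare, short, and
  typically absorbed or discarded by the 80-ms minimum).
* Zero net gaze makes coverage undefined (`NA`), reported as missing.
* Trials spanning less than the ten complete bins abort the binning with an
  error naming the trial; the pipeline excludes and logs them.
* Per-trial seeds derive deterministically from (master seed, participant,
  trial index), so any subset of an experiment reproduces bitwise.

## Problem sizes

The test suite exercises the I-VT/oracle equivalence and conservation
identities on 1,000 simulated streams, and the full parameter-recovery study
at the published scale — 240 stimuli (40 models × 6 expressions) × 20
simulated observers, 4,800 trials — through the entire pipeline. These sizes
were chosen to match the study design while keeping a full run of suite plus
acceptance script in the low minutes on a single core.

## Known limitations

* ROI geometry is a parameterized default (band fractions of the face box),
  not digitized published region outlines; absolute pixel agreement with any
  specific stimulus set requires supplying the real polygons via the config.
* Gaze-duration attribution by fixation centroid versus by sample is an
  analysis choice the package exposes but cannot adjudicate; defaults favor
  internal consistency.
* The split-plot ANOVA assumes complete, balanced within-item data and
  refuses anything else rather than guessing a Type-II/III strategy.
* By-items aggregation treats observers as exchangeable replicates; no
  crossed participant × item mixed-effects model is provided.
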