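# facegaze

Eye-tracking analysis of how observers look at **dynamic facial expressions
of emotion** — and a seeded synthetic scanpath generator that makes the whole
chain testable without raw recordings.

When a face unfolds from neutral to emotional over about a second, each
emotion's *diagnostic* region (frowning brow for anger and sadness, smiling
mouth for happiness, wrinkled nose/cheek for disgust) attracts fixations
selectively. `facegaze` takes raw 500-Hz gaze sample streams recorded over
1,033-ms expression clips and produces, for researchers in visual cognition
and affective science:

* **I-VT event detection** — angular speed by central differences; samples
  above a 40 °/s threshold are saccades, below-threshold runs of ≥ 80 ms are
  fixations; blinks and dropouts (invalid runs) are excluded, yielding *net*
  gaze.
* **Region-of-interest metrics by items** — for the eye, nose/cheek and
  mouth regions: probability of first fixation (after the carried-over
  central fixation), probability and time of entry, net gaze duration and
  number of fixations, averaged across observers for each of the 240 stimuli
  (40 models × 6 expressions).
* **Gaze time course** — net gaze binned into ten 100-ms intervals (the
  final 33 ms of the clip discarded); for each region the **threshold**
  (earliest bin in which an expression's gaze proportion significantly
  exceeds every comparison expression's) and the **amplitude** (number of
  consecutive bins the advantage persists).
* **Categorization performance** — 6 × 6 stimulus-by-response confusion
  matrix, hits, hit reaction times and modal confusions; the published norm
  table ships as a plain-text fixture.
* **By-items inference** — one-way and split-plot (expression × region)
  ANOVAs with partial eta squared
  (η²ₚ = SS_effect / (SS_effect + SS_error)), single-step Bonferroni
  pairwise contrasts (p·m capped at 1), and compact letter displays in which
  groups share a letter iff they do not differ significantly.

The synthetic generator (`simulate_trial()`, `simulate_experiment()`)
produces streams with the structure the analysis assumes — an initial
fixation on the nose carried over from the fixation cross, log-normal
fixation plateaus, 300 °/s saccade ramps, optional blinks, dwell weights
that become expression-specific once the expression is discriminable, and
multinomial categorization responses — so parameter recovery can be verified
at the full study scale.

## Worked example

Simulate the full design — 240 stimuli × 20 observers — and run the
pipeline (1–2 minutes on one core):

```r
library(facegaze)

screen <- default_screen_geometry()
rois   <- build_default_rois(face_box_for_angle(screen))
reg    <- stimulus_registry(40)                    # 240 clips

ex  <- simulate_experiment(20, reg, default_attention_profiles(),
                           default_confusion_model(), simulation_config(),
                           rois, screen, seed = 42)
rep <- run_pipeline(ex$streams, ex$trials)

round(with(rep$item_norms, tapply(gaze_eyes, expression, mean)))
#>     anger   disgust      fear happiness   sadness  surprise
#>       418       290       325       243       407       330

advantage_profile(rep$timecourse, "happiness", "mouth")[
  c("threshold_bin", "amplitude_bins")]
#> $threshold_bin  [1] 5        # the 401-500-ms interval
#> $amplitude_bins [1] 6        # advantage persists through 1,000 ms

round(100 * rep$confusion$prop["fear", ], 1)
#> happiness  surprise     anger   sadness   disgust      fear
#>       0.6      24.0       1.4       2.5      10.6      60.9

subset(rep$anova_tables, measure == "gaze" & roi == "eyes")[
  , c("expression", "mean", "letters", "F", "partial_eta_sq")]
#>  expression mean letters    F partial_eta_sq
#>       anger  418       a 75.1          0.616
#>     sadness  407       a 75.1          0.616
#>    surprise  330       b 75.1          0.616
#>        fear  325       b 75.1          0.616
#>     disgust  290       c 75.1          0.616
#>   happiness  243       d 75.1          0.616
```

Reading the output: anger and sadness draw the most eye-region gaze and
share letter *a* (statistically equivalent, different from everything else);
the happy mouth's attentional advantage emerges in the fifth 100-ms bin and
persists for six consecutive bins; simulated fear stimuli are confused mainly
with surprise (24.0% of responses), mirroring the programmed confusion
norms. All of this recovers the generator's programmed attention profiles —
which encode the qualitative published pattern — through the complete
detection-to-inference chain.

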