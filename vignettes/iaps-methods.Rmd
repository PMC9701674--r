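---
title: "Measuring gaze–gesture intrapersonal synchrony: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gaze–gesture intrapersonal synchrony: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, algorithms and parameter choices behind
`iapsync`, in the spirit of a methods section: what each stage assumes, which
knobs matter, why the defaults are what they are, and what the validation
suite does and does not establish.

## The measurement target

In a structured reference task, a participant indicates the location of a
target to a partner using gaze and a pointing gesture. The quantity of
interest is the per-trial *gaze–gesture delay*

```
delay [ms] = t(gesture onset) − t(communicative gaze-shift onset)
```

and its within-subject variability (the SD of delays per subject × block ×
target side). A *communicative gaze shift* is a saccade that starts in the
partner's face region (the social RoI) and ends on the target stimulus RoI.
Group inference compares an autism-diagnosed (ASD) and a typically-developed
(TD) comparison group on both indices with mixed models.

## Gaze-event parsing

Raw input is a 1000 Hz stream of `(time_ms, x_px, y_px, valid)` samples.
Events are detected offline:

* **Velocity estimation.** Positions are converted to degrees of visual
  angle per axis (`atan(offset_mm / distance_mm)`, default geometry:
  1920 × 1200 px panel, 518.4 × 324 mm, 940 mm viewing distance), then
  differentiated with a 5-point central difference and combined into speed.
  A width-3 boxcar smooths the speed series.
* **Saccades.** Runs of smoothed speed ≥ 30°/s lasting ≥ 4 ms. The 30°/s
  criterion is the one published number for the reference tracker's parser;
  the stencil, smoothing width and the 4 ms minimum duration are this
  package's documented substitutes for proprietary parser internals (an
  acceleration criterion we do not reproduce). The minimum-duration gate
  suppresses single-sample noise triggers.
* **Blinks.** Maximal runs of invalid (pupil-lost) samples. Saccade-like
  runs within 20 ms of a blink edge are absorbed into the blink — the
  standard guard against the velocity artifacts that pupil occlusion
  produces at blink boundaries.
* **Fixations.** Everything else. Events use half-open intervals
  `[onset, offset)` in integer ms and tile the trial exactly; this tiling is
  asserted by property tests.

Raising the velocity threshold can only shrink supra-threshold runs, so on
the package's synthetic streams (whose saccades have unimodal velocity
pulses) the saccade count is monotone non-increasing in the threshold —
also a property test.

## Communicative gaze-shift selection

Fixations are RoI-labelled by centroid; the social RoI is a square above the
screen's top edge (the partner's face, visible because the monitor is
lowered), the stimulus RoIs are rectangles in the upper screen half, and
everything else is "random". Boundaries are inclusive on min edges,
exclusive on max edges. Three saccade pathways qualify, anchored in a
social-RoI fixation and ending in a fixation on the target RoI:

1. direct saccades (candidate = the saccade itself),
2. chains with one intermediate *social* fixation (candidate = the second
   saccade),
3. chains with one intermediate *random* fixation (candidate = the first
   saccade).

Chains are capped at one intermediate fixation, matching the three
enumerated pathways. A fixation on the non-target stimulus bar is *not* a
valid intermediate: it lands in a defined RoI, not a "random" one. Both
caps are documented package decisions where the originating description is
silent.

Selection applies six exclusion rules in a fixed order (their listing
order; the source never states a precedence, so this is a documented
assumption), returning the lowest-numbered violated rule:

1. first trial of each block;
2. gaze not in the social RoI at the stimulus-onset *sample* (the sample,
   not its enclosing fixation, for robustness to parser boundary jitter);
3. no candidate pathway;
4. a blink ending within 100 ms before stimulus onset or spanning it;
5. pathway latency < 75 ms — evaluated on the *first* saccade of the
   candidate's pathway, because the externally-triggered argument concerns
   the initial orienting movement;
6. gesture onset preceding the candidate saccade onset.

A missing gesture onset when rule 6 must be evaluated yields the distinct
code `indeterminate_gesture`. Widening the blink window can only move
trials from selected to excluded (tested). Rule 6 guarantees non-negative
delays.

## Delay metrics

Delays are integer ms. Aggregation levels: subject means (all trials per
subject) and sample SDs (n−1) per subject × block × side; cells with one
observation yield no SD and are dropped with a message. Extreme values are
flagged per group outside `Q1 − 3·IQR` / `Q3 + 3·IQR`, with quartiles by
linear interpolation between order statistics (`quantile()` type 7 — the
convention is unstated in the source, so the package fixes one and exposes
it). Channel-use coding turns rater annotations (verbal, gesture) plus the
selector outcome (gaze = 1 iff selected) into six *mutually exclusive*
combination flags and three count flags; exclusivity is a package decision —
without it the six flags plus the counts would double-count trials. First
trials are excluded from channel data just as the selector excludes them.

## Gesture kinematics from video

Frames (30 fps RGB) are processed per frame within an image RoI: median
filter per channel (3 × 3), per-channel threshold ranges whose conjunction
forms the colour mask (red cap = left index finger, blue = right), largest
connected component above a minimum area, shrink-to-point via centroid.
Absent detections stay in the series as not-present points.

Trajectories are Gaussian-kernel smoothed (default bandwidth 1 frame — wide
enough to damp centroid quantization, narrow enough not to smear movement
onset into rest), and segmented by a double threshold: a movement triggers
where frame-to-frame speed stays ≥ 1 px/frame for ≥ 3 frames, and its
boundaries extend outward while the speed exceeds 10% of the trigger. The
extension recovers the slow tails of a ballistic stroke so that durations
are not truncated at the trigger threshold.

Per segment: **amplitude** = start-to-end displacement in mm (the ballistic
pointing reading of "amplitude"; path length is exposed as an auxiliary
output), **mean velocity** = path length / duration in mm/ms, duration from
the frame count at 30 fps. Amplitude and mean velocity are invariant to
rotation and translation up to pixel quantization (tested). On noise-free
rendered videos, recovery of programmed amplitude and mean velocity is
well under the 2% / 5% bands the validation suite asserts.

## Mixed-model inference

`iaps_fit(formula, data, test = "group", family)` fits the alternative
model (the formula) and the null model with the tested fixed term removed,
both by maximum likelihood, and reports the likelihood-ratio test
(χ² = 2Δℓ, df = parameter difference, upper chi-square tail). Estimation
delegates to `lme4`/`lmerTest`; the package's contribution is the nested
comparison, the fallback and the diagnostics:

* **Coefficients.** Gaussian models: Satterthwaite df, p-values and
  t-interval CIs (via `lmerTest`). Binomial models: Wald z and normal CIs —
  Satterthwaite approximations are not defined for GLMM deviances, so Wald
  is the package's documented choice.
* **Convergence fallback.** If a random-slopes model fails to converge
  (optimizer convergence warnings/errors — boundary-singular fits alone do
  not trigger it), both models are refitted with random intercepts only,
  with a message and a `fallback` flag. This mirrors the standard practice
  of simplifying the random-effects structure when the data cannot support
  it, e.g. for the SD-of-delays response where aggregation leaves few
  observations per cell.
* **Complete separation.** For binomial responses, if any level of the
  tested factor has a constant outcome, the `separation` flag is set and a
  warning marks the coefficient's inference unreliable (its ML estimate
  diverges; the LRT remains informative).

The LRT statistic is clamped to zero within 1e−6 (optimizer tolerance);
a more negative value errors as evidence of non-nested models.

Group-comparison dispatch for characteristics tables follows the
conventional decision tree: Shapiro–Wilk non-normality in either group →
Mann–Whitney with effect size r = |Z|/√N (Z from the tie-corrected normal
approximation); otherwise Bartlett heterogeneity → Welch t with
Welch–Satterthwaite df; otherwise Student t. Cohen's d defaults to the
equal-weight pooled SD `sqrt((sd1² + sd2²)/2)` (the convention for
independent, (near-)equally sized groups; the (n−1)-weighted variant is
available). The same statistics are recomputable from printed M/SD/n
summaries — the Bartlett dispatch needs only those. Multiple-comparison
adjustment defaults to Benjamini–Hochberg: step-up FDR control is the
procedure consistent with families of corrected p-values that tie at a
common value, which is the pattern these analyses produce.

## The synthetic cohort generator

The generator replaces unavailable participant data and defines the
conditions under which the pipeline is validated.

**Design.** Two groups of 24 subjects, 4 blocks × 30 trials, target side
counterbalanced within block (15/15, shuffled). 1000 Hz streams with
stimulus onset at 400 ms and 1100 ms post-onset.

**Delay structure.** Per subject, (mean delay, within-subject SD) is drawn
from a bivariate lognormal — delays are positive and right-skewed, and the
lognormal makes the documented positive mean–SD coupling natural
(log-scale correlation 0.6). Moments are matched so that the TD group mean
is 206 ms with between-subject SD 59 ms, the ASD group is shifted by
+55 ms (mean 261 ms) with between-subject SD 103 ms, and expected
within-subject SDs are 81 ms (TD) and 95 ms (ASD) with log-scale dispersion
0.45 — all taken from the printed group descriptives the generator
emulates. The ASD between-subject SD is a package addition: without it the
ASD group's printed dispersion cannot be reproduced. Per-trial delays are
Gaussian about the subject mean, truncated at zero by resampling (the
selection rules guarantee non-negative delays; truncation shifts means by
< 1 ms at these parameters).

**Gaze streams.** Piecewise fixation–saccade–fixation geometry. Saccade
latency is uniform on [120, 300] ms — a placeholder, documented as such,
since no stimulus-locked latency distribution is available to emulate; its
lower edge stays far above the 75 ms rule so parser jitter cannot flip the
rule. Saccades move along straight lines in angular space under a
raised-sine velocity pulse with constant-slope edges (edge speed ≈ 80°/s,
scaled down for small saccades) and main-sequence durations
(≈ 2.2·amplitude + 21 ms). The edge slope is chosen so that the parser's
first supra-threshold sample *is* the programmed onset under the package's
5-point-difference + boxcar pipeline: the generator and parser agree on
what "onset" means, which is what lets ground-truth labels be recovered
exactly rather than to within a tolerance.

**Position noise defaults to 0 px.** At 1000 Hz, central differences
amplify even sub-pixel position noise to tens of °/s, i.e. real parsers
survive noise through filtering that inevitably shifts onsets by a few ms.
The generator's contract — selector label agreement of 100% and delays
equal to truth *exactly* — is a statement about clean event geometry, so
clean geometry is the default; a `noise_px` key exists for robustness
experiments, where recovery is within ±2 ms rather than exact.

**Exclusions.** First trials are always labelled. The other five rules are
injected with rates (8%, 4%, 3%, 2%, 1%) calibrated once so that the share
of analyzable trials (~82% of non-first trials) matches the printed trial
accounting of the emulated study; per-category frequencies are not
published, so the split across rules is an assumption. Each injected
violation is constructed to violate only its rule and no rule of higher
precedence (e.g. pre-onset blinks end 5–95 ms before onset; benign blinks
on clean trials end ≥ 130 ms before onset, outside the 100 ms window with
margin).

**What passing does and does not show.** Perfect label recovery and exact
delay recovery on this generator validate the algorithmic chain — the
parser's thresholding, the pathway logic, rule precedence, the arithmetic.
They do not certify performance on real recordings, whose noise, drift,
head motion, irregular saccade kinematics and idiosyncratic blink artifacts
the generator deliberately does not model (nor does it render photorealistic
hands; gesture video is a disc of the cap colour on a grey background).

## Validation studies and problem sizes

The acceptance suite runs, at sizes chosen to keep the full suite in the
minutes range on one CPU:

* selector ground-truth recovery on one full cohort (48 subjects, 5,760
  trials): accuracy must be 1;
* group-shift recovery: 50 simulated cohorts at study scale with the
  programmed +55 ms shift, random-intercept LMMs (the generator programs no
  block/side slope variance, so slope models are boundary-singular there
  and add only runtime); the mean recovered β must lie within ±10 ms of 55;
* LRT type-I calibration: 200 null simulations from the Gaussian
  random-intercept model at study scale (24/group × 110 trials,
  σ_subject = 59, σ_resid = 81); the rejection rate at α = 0.05 must lie in
  [0.02, 0.09]. This calibrates the test under its own assumptions. Note
  that under the full generator's heavy-tailed subject-level distribution
  the nominal chi-square reference is expected to be mildly anticonservative
  — a known property of likelihood-ratio tests under non-normal random
  effects, worth remembering when applying the pipeline to skewed data;
* trajectory recovery on rendered videos (2% amplitude, 5% mean velocity)
  and trajectory-LMM type-I at the kinematics level over 200 replicates
  with identical group distributions;
* oracle equivalences: RoI assignment, extreme-value fences, SD
  aggregation, Welch df, Benjamini–Hochberg — each against an independent
  brute-force implementation on randomized inputs.

## Numerical conventions and degenerate inputs

All times are integer ms with stimulus onset defining trial time zero in
reports; event intervals are half-open; coordinates are 0-based pixels,
origin top-left, y downward. Candidate pathways tie-break by scan order
(earliest anchoring saccade first), which resolves the ambiguity between a
social-refixation chain and its embedded direct reading in favour of the
chain. Parsing requires ≥ 3 valid samples; aggregation requires non-empty
groups; fence flagging requires ≥ 4 values per group (warning otherwise);
`pearson_cor` requires n ≥ 4 and non-degenerate variance; all-equal values
flag nothing (fences collapse onto the common value).

## Known limitations

* The parser is offline and intentionally simple; it is not a reimplementation
  of any proprietary tracker parser, and its minimum-duration and smoothing
  choices are substitutes for unpublished internals.
* The generator's saccade latency distribution and exclusion-rate split are
  placeholders; conclusions that depend on them (e.g. exact exclusion
  tallies) are structural, not empirical.
* Amplitude is defined as stroke displacement; analyses that intend path
  length should use the auxiliary `path_mm` output.
* Binomial-model inference under complete separation is flagged but not
  regularized; users needing estimates under separation should turn to
  penalized likelihood approaches outside this package's scope.
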