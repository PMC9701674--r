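# iapsync

Intrapersonal synchrony (IaPS) is the temporal alignment of communication
signals produced by one person — here, the delay between the onset of a
*communicative gaze shift* (a saccade that starts on an interaction partner's
face and lands on a target stimulus) and the onset of the pointing gesture
that refers to the same target. Enlarged and more variable gaze–gesture
delays have been proposed as an objective behavioural marker of autism
spectrum conditions, so the millisecond-scale measurement and group
comparison of these delays is of direct clinical-research interest.

`iapsync` is an R package for analysts working with high-rate eye-tracking
and gesture-video data from structured two-person reference tasks. It
implements the full measurement chain:

1. **Gaze parsing** — a velocity-threshold event parser for 1000 Hz gaze
   samples (30°/s criterion, 5-point central differences, boxcar smoothing,
   blink handling) with region-of-interest (RoI) labelling.
2. **Communicative gaze-shift selection** — classification of the three
   admissible gaze pathways (direct, social-refixation, random-refixation)
   and six ordered exclusion rules (first trial of block; gaze not on the
   partner's face at stimulus onset; no communicative shift; blink within
   100 ms before onset; saccade latency < 75 ms; gesture before gaze).
3. **Delay metrics** — per-trial delays
   `delay = t(gesture onset) − t(gaze-shift onset)`, subject-level means,
   within-subject SDs per subject × block × side, per-group 3 × IQR
   extreme-value fences, and binary channel-use coding for free-response
   trials.
4. **Gesture kinematics from video** — colour-blob fingertip tracking at
   30 fps (RGB thresholding, largest connected component, shrink-to-point),
   kernel smoothing, movement segmentation, and amplitude / mean-velocity
   aggregation.
5. **Inference** — `iaps_fit()`, a formula-interface mixed-model comparison:
   for response *y*, subjects *s* and design factors block *b* and side
   *d*, the alternative model

   *y<sub>ist</sub>* = β₀ + β₁ group*<sub>i</sub>* + β₂ *b* + β₃ *d* +
   *u<sub>s</sub>* + ε*<sub>ist</sub>*

   is fitted by maximum likelihood (lme4) against the null model without
   the group term and compared with a likelihood-ratio test,
   χ² = 2(ℓ₁ − ℓ₀) on 1 df. Coefficients carry Satterthwaite p-values and
   confidence intervals; random-slope structures fall back to random
   intercepts on convergence failure (reported, never silent); complete
   separation of binomial outcomes is flagged. Group-comparison dispatch
   (Shapiro–Wilk → Mann–Whitney with r = |Z|/√N; Bartlett → Welch *t* with
   Welch–Satterthwaite df; otherwise Student *t*), Cohen's *d* (equal-n
   pooled SD √((s₁² + s₂²)/2)), Pearson correlations with Fisher-z
   intervals, and Benjamini–Hochberg adjustment round out the toolkit.

Because raw participant data of the motivating study design are not openly
available, the package ships a **synthetic cohort generator**
(`simulate_cohort()`) that emulates the design — two groups of 24 subjects,
4 blocks × 30 trials, counterbalanced target sides — with complete ground
truth: programmed gaze streams, shift onsets, delays, pathway labels and
labelled violations of every exclusion rule. All validation is against this
generator.

## Worked example

```r
library(iapsync)

cfg <- cohort_config(seed = 2026)        # 24 subjects/group, 4 x 30 trials
cohort <- simulate_cohort(cfg)           # gaze streams + ground truth
selection <- select_cohort(cohort)       # parse + select per trial
validate_selection(selection, cohort$truth)$accuracy
#> [1] 1

delays <- compute_delays(selection, cohort$trials)
subj <- aggregate_delays(delays, "subject")
delay_descriptives(subj)
#>   group     M    SD   Mdn    min   max  n
#> 1   ASD 233.1 82.20 214.6  89.39 423.7 24
#> 2    TD 185.8 40.35 184.0 118.78 290.6 24

d <- delays; d$block <- factor(d$block); d$side <- factor(d$side)
fit <- iaps_fit(delay ~ group + block + side + (1 | subject), d)
fit
#> Mixed-model comparison (gaussian, ML): term 'group'
#>   LRT: chisq(1) = 6.26, p = 0.01236
#>   groupTD: beta = -47.28, 95% CI [-84.05, -10.51], p = 0.01282
```

The selector reproduces every generated exclusion label (accuracy 1), the
group descriptives reflect the generator's programmed group means (TD mean
delay 206 ms, ASD shifted by +55 ms, with large between-subject spread), and
the likelihood-ratio test detects the group shift: the TD group's delays are
estimated 47 ms shorter than the ASD group's in this cohort (the programmed
shift is 55 ms; the estimate varies across cohorts with the between-subject
dispersion).

Effect sizes can be recomputed directly from printed group summaries:

```r
cohens_d(206.02, 59.45, 24, 264.05, 103.13, 24)
#> [1] -0.6894156
```

## Package layout

- `R/` — implementation (generator, parser, selector, metrics, video,
  inference, pipeline); `run_pipeline()` orchestrates the whole chain and
  writes a CSV/JSON report bundle.
- `vignettes/iaps-methods.Rmd` — the methods vignette: model assumptions,
  parameter choices, generator design, and known limitations.
- `tests/testthat/` — unit, property and acceptance tests.
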