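---
title: "Methods: screening for high autistic traits from shape-drawing kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for high autistic traits from shape-drawing kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drawscreen)
```

## The problem and the data

Five-year-old children copy four shapes — equilateral triangle,
inverted equilateral triangle, square, sun — on an LCD pen tablet after
watching a demonstration video for each shape. The tablet streams, at
30 Hz: pen-tip x/y (relative screen coordinates in [0,1]), pen pressure
([0,1]), pen azimuth ([0,360) degrees) and pen tilt ([0,90] degrees).
A webcam above the screen provides gaze rotation about the horizontal
and vertical axes ([-90,90] degrees), synchronized to the same clock.
Each participant therefore contributes 4 shapes x 2 phases
(demonstration, drawing) of multichannel time series, plus metadata:
sex, age, and the parent-rated SRS-2 T-score. Participants whose SRS-2
exceeds the sex-specific screening cutoff (boys 53.5, girls 52.5) form
the high-trait group; the reference cohort has 20 high and 113 low.

The scientific question is whether the *process* of drawing — not the
drawn product — predicts high-trait membership well enough to serve as
an objective screening instrument.

## Segmentation

Children lift the pen between strokes. An *active drawing segment* is a
maximal run of samples with pressure above a contact threshold
(default 0: any contact counts), kept if at least `min_len = 3` samples
long (0.1 s at 30 Hz, suppressing single-frame contact glitches). Both
thresholds are exposed in `featureConfig()` because the original
preprocessing rule is not published in the article text. All pen
features pool samples across a recording's segments, and *no first
difference is ever taken across a segment boundary* — a pen-up gap is
not a pressure change or an acceleration.

## The sixteen features

For pressure, tilt and speed the statistics are ordinary: mean and
sample SD (n-1 divisor; the divisor is not stated in the source, so the
unbiased convention is used throughout, and the tests' oracle uses the
same). Speed between consecutive pen-down samples is the Euclidean step
length divided by the actual inter-sample interval (screen units/s).

Two conventions deserve justification:

* **"Mean change" features** (`Mpenpressurechange`,
  `Mdrawingacceleration`, `Mpentiltchange`, `Mpenorientationchange`)
  are mean *absolute* per-sample first differences. A signed mean would
  telescope to (last - first)/n and measure nothing but drift; the
  absolute difference measures the jitter these features are meant to
  capture. Signed and per-second variants are available via
  `featureConfig(change = "signed", per_second = TRUE)`.
* **Orientation is circular.** Azimuth lives on [0,360); naive
  arithmetic would call 350 degrees and 10 degrees far apart. The mean is the
  circular mean direction, the SD is sqrt(-2 log R) in degrees (R the
  mean resultant length), and differences are wrapped to [0,180]. Since
  the original analysis may well have used raw angles,
  `featureConfig(orientation_stats = "linear")` restores that behavior.

The four gaze-coupling features are zero-lag product-moment
correlations: during the demonstration, gaze vs the advancing line's
tip over all frames; during drawing, gaze vs the child's pen tip over
pen-down samples only (pen-up excursions are saccade targets, not
tracking). Pairs with missing gaze are dropped pairwise. A correlation
with fewer than 10 valid pairs or a zero-variance signal is *invalid*:
it is imputed with 0 — the "no linear coupling" value — and flagged in
the feature vector's validity mask, keeping the design matrix complete
for the SVM without inventing coupling that was not observed.

## The screening model

The classifier is a linear soft-margin SVM (via `e1071`/libsvm, cost
grid `10^-3 ... 10`). Features are z-scored *inside each
cross-validation fold* using only the training rows; the article does
not state its scaling, but a cost of 0.001 — the value every reported
model used — is only meaningful on standardized features, and per-fold
scaling avoids information leaking from the held-out participant.

Feature subset and cost are selected *jointly* by maximizing
leave-one-out accuracy, with ties broken by (1) higher sensitivity —
a screening instrument should find the high-trait children, (2) fewer
features, (3) lower cost. Comparisons use exact integer counts (number
correct, number of true positives), never floating-point accuracies.
The default search is greedy sequential floating forward selection
(add the best feature while the criterion improves; then drop any
feature whose removal improves it); `search = "exhaustive"` scores
every subset and is used in tests as an upper bound on the greedy
search for small candidate sets. The per-shape models draw from the 16
features of that shape; the "all features" model draws from the 64
shape-suffixed features.

Probabilities of high-trait membership come from a Platt sigmoid
`P(high | f) = 1/(1 + exp(A f + B))` fitted on the training fold's
decision values with the usual prior-smoothed targets, by BFGS from a
deterministic initialization. This is implemented in the package rather
than taken from libsvm's `probability = TRUE`, whose internal five-fold
shuffle cannot be seeded through `e1071` — leave-one-out results here
must be bit-reproducible.

**Selection optimism.** The accuracy reported for a selected model is
optimized by the same leave-one-out estimate that selection searched,
so it is biased upward. `nestedLoocvAccuracy()` re-runs the *entire*
search inside an outer leave-one-out loop and reports the unbiased
estimate; the package's calibration tests check that on null data the
nested estimate stays within 0.10 of the majority-class rate while the
selection-optimized estimate exceeds it. Reported per-shape metrics
should always be read alongside this gap.

## Shapley interpretation

For a linear decision function the Shapley value of feature j for
participant i has the exact closed form
`phi_ij = w_j (x_ij - mean_j(background))` under the interventional
expectation, and local accuracy `base + sum_j phi_ij = f(x_i)` holds to
machine precision. The background is the full cohort being explained —
the natural reference population for a screening model. Attributions
are computed on the decision function, not the calibrated probability,
because exactness holds only there; the ranking by mean absolute
contribution is unaffected by the monotone sigmoid's direction.

## The synthetic cohort generator

The generator exists so that segmentation, extraction, model selection
and interpretation can be exercised and *calibrated* end to end without
clinical recordings. Its defaults encode the reference study
conditions:

* **Group sizes 20/113, sex ratio 70:133.** Age ~ Normal(5.05, 0.17)
  truncated to [4.5, 5.5] years (the cohort was recruited at age five;
  the exact distribution is unpublished, so a truncated normal matching
  the printed means/SDs is used).
* **SRS-2 scores.** Low group: normal(32.06, 11.26) truncated to
  [0, cutoff]. High group: cutoff + a shifted gamma matched to the
  printed mean/SD offset (68.15 ± 23.68 relative to the cutoff). A
  plain normal for the high group would put roughly a quarter of its
  draws below the screening cutoff, making the group labels
  inconsistent with the cutoff rule; the gamma preserves consistency,
  approximates the printed moments, and reproduces the right skew such
  screening distributions show. Scores are rounded to integers
  (T-scores are integers; the half-point cutoffs then make ties
  impossible).
* **Drawing profiles.** Each participant draws a latent profile of 12
  parameters (pressure mean/SD/roughness, speed/CV/roughness, tilt and
  azimuth mean/SD/roughness), one per pen feature, so a standardized
  effect `d` requested for a feature is applied as `base + bsd * d` to
  exactly that parameter. Within a recording, channels follow AR(1)
  noise whose lag-1 correlation is `1 - r^2/2` for roughness `r`,
  making the mean absolute first difference proportional to `r` — the
  knob behind the three "change" features. Strokes follow the template
  polylines (sun = 36-gon circle + 8 rays; stroke counts and order per
  the published stroke diagrams) at the profile's speed; pen-up gaps of
  0.2-0.5 s with pressure exactly 0 separate strokes so segmentation is
  genuinely exercised.
* **Gaze.** The gaze channel is built by an exact-correlation
  construction: the standardized reference trajectory plus an
  orthogonalized noise vector, mixed so the *sample* correlation over
  the correlation support equals the requested coupling exactly (it is
  scaled to a 12-degree excursion, far from the +/-90 clamp). Couplings
  are drawn per participant (SD 0.12 around the group target, default
  0.75 low / 0.45 high) with small per-recording, per-axis jitter.
* **Default effect map.** Shifts of d ~ 1.0-1.2 on the pen features
  (heavier/more variable pressure, slower/jerkier movement, less stable
  pose in the high-trait group, signs following the handwriting
  literature) plus the coupling gap above. These were fixed from an a
  priori power argument: the reference models reach >= 85% on all three
  metrics with 100% specificity, which requires a cohort-level
  Mahalanobis separation around 4-5; the defaults produce that regime
  without making any single feature a giveaway. They are calibration
  choices — the study does not publish per-feature group summaries to
  anchor them.

What the generator does **not** emulate: shape-dependent difficulty,
within-participant learning or fatigue across the four shapes,
OpenFace's gaze-estimation error structure (heavy-tailed, blink gaps),
redraw-after-deviation events, or any correlation between SRS-2 score
and drawing behavior *within* a group (traits enter only through the
group label). Passing calibration tests on this cohort therefore shows
the pipeline recovers the structure it is pointed at — not that the
real effect sizes equal the defaults.

## Numerical choices and degenerate inputs

* Comparisons in the model search are integer-exact; accuracy values
  are derived afterwards.
* A zero-variance feature column gets scale 1 during standardization
  (the column contributes nothing either way).
* A leave-one-out fold whose training set is single-class (possible
  only when a class has one member) predicts the training class and is
  flagged with a warning rather than failing the whole evaluation.
* Circular means at the 0/360 wrap are canonicalized to 0; the circular
  SD's resultant length is clamped to 1 before the log.
* Segmentation with no qualifying run yields an empty segment table;
  feature extraction on it raises "no active drawing" naming the
  participant and shape.
* The exact-correlation gaze construction needs at least 3 support
  samples and a non-flat reference; a flat reference (a child holding
  the pen still) produces pure noise, which the extraction stage then
  flags as an invalid correlation.

## Problem sizes used by the test suite

The suite runs the full study size (133 participants) where a single
search is involved (per-shape model selection), and reduced sizes where
repetition is: planted-signal recovery uses 20 seeds at n = 60 (15/45)
— large enough that a noise feature cannot routinely substitute for a
planted one once accuracy saturates — and the null nested-LOOCV
calibration uses n = 40 (8/32) with 6 candidate features and at most 3
selected. These sizes are the package's choice of desk-scale
calibration experiments; the statistical thresholds they check
(t beyond 5 under d = 2, |t| <= 3 under the null, accuracy within 0.10
of the majority rate, mean planted-model accuracy >= 0.95) are
inherited from the method's own claims.

## Known limitations

* The published per-shape results were obtained with an unpublished
  search procedure; this package's greedy-floating default is a
  principled reconstruction, bounded empirically by the exhaustive mode
  on small candidate sets, but it need not visit the same subsets.
* The sex-ratio chi-squared published for the reference cohort (0.474)
  is not reproducible from its published counts (12:8 vs 58:55) by
  either the standard (0.513) or continuity-corrected (0.224) formula;
  `pearsonChi2()` reports the standard formula. Likewise the published
  age t (1.273) differs slightly from the value implied by the rounded
  group summaries (1.21); the published df (26) does reproduce.
* With 20 positive cases, a single misclassified high-trait child moves
  sensitivity by 5 percentage points; all reported metrics should be
  read with that granularity in mind.
* Leave-one-out cross-validation was chosen by the reference analysis
  for its small cohort; the package reports the nested estimate so the
  cost of that choice (selection optimism) is visible rather than
  hidden.
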