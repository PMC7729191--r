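---
title: "Kinematic predictors of arousal ratings: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematic predictors of arousal ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facekin)
```

## The scientific problem

Observers can judge how *aroused* (activated, excited) a person looks from
their facial expression, but it is not obvious which physical properties of
the moving face carry that information. facekin operationalizes the
candidate cues from automated 68-landmark face tracking of short expression
videos (neutral face, rise to an emotional peak, return to neutral):

* **Displacement** — how far the face is from a baseline configuration. This
  is a *static* cue: it can in principle be read off a single frame.
* **Speed** and **acceleration magnitude** — how fast the configuration
  changes, and how suddenly. These are *dynamic* cues requiring a sequence.

The package computes these cues per clip, explores their correlation
structure to pick non-collinear predictors, and relates the chosen predictors
to per-clip mean arousal ratings collected from neurotypical (NT) raters,
raters with an autism diagnosis (ASD), and optionally further panels such as
high-autistic-traits (HAT) raters, including a between-group difference
model.

## Normalization

Raw tracking coordinates confound expression with the position, size and
orientation of the face in the camera frame. All frames of **all** clips of a
study are therefore pooled into a single Generalized Procrustes
superimposition (`normalize_study()`): every frame is centered, scaled to
unit centroid size, and iteratively rotated onto a consensus configuration
that is re-estimated as the per-coordinate mean until it is stable to a
relative tolerance of `1e-8` (at most 100 iterations; non-convergence is a
recorded warning, not an error). Pooling is essential: baselines extracted
from different clips must live in the same coordinate frame to be
comparable.

Numerical choices worth knowing:

* 2-D optimal rotations have a closed form
  (`atan2(sum(x*y' - y*x'), sum(x*x' + y*y'))`); no SVD is needed.
* Reflections are forbidden by default (faces have handedness); a config
  flag permits them.
* The consensus update (the renormalized mean) is the constrained optimum,
  so the total Procrustes residual is non-increasing across iterations — a
  property the test suite asserts.
* A pure rotation of the whole constellation leaves the residual unchanged
  (a gauge freedom), so the updated consensus is re-aligned to the previous
  one before testing convergence, and the final consensus is canonicalized
  by rotating its principal axis onto +x with the sign of the third moment
  fixing the remaining half-turn. Repeated runs and permuted inputs thus
  give identical output frames.
* With wildly dissimilar configurations (e.g. i.i.d. random point clouds)
  generalized Procrustes analysis can have multiple fixed points, and input
  order can select among them. In the regime the package is used in —
  thousands of frames of the same faces — the optimum is unique in practice;
  the order-invariance test uses that regime deliberately.
* Rotation removal is on by default but exposed as a flag
  (`include_rotation`), since location/size-only normalization is a
  defensible alternative reading of the procedure.

## The eight measures

For a normalized clip with frames `f = 0..T-1`, per-landmark Euclidean
displacement is summarized by the root-mean-square deviation
`RMSD(a, b) = sqrt(mean_p d(p_a, p_b)^2)`. Squaring before averaging means
opposite motions of different landmarks accumulate instead of cancelling.
Three series are derived:

| series | definition | support |
|---|---|---|
| distance | `RMSD(frame_f, baseline)` | `T` |
| speed | `RMSD(frame_f, frame_{f+1})` (time unit = frame) | `T - 1` |
| acceleration | RMS of per-landmark `(v_{f+1} - v_f) / 2` magnitudes | `T - 2` |

Two baselines are supported: the **clip-neutral face** (the clip's first
frame) and the **actor-mean face** (the per-coordinate mean over all frames
of all clips of that actor, so longer clips weigh proportionally more).
Baselines are taken *after* normalization; unnormalized baselines would make
cross-clip distances incommensurable. Each series is aggregated over its own
support by `mean` and `max`, giving the eight per-clip measures
(`measure_names()`); `mean <= max` holds for each pair by construction.

The acceleration window divides the velocity difference by its 2-frame
length by default. The undivided difference is a defensible alternative
convention, exposed as `accel_denominator = 1`; the two differ only by the
constant factor 2 and are therefore equivalent for any correlation-based
analysis.

Time is measured in frames throughout. None of the downstream analyses
depend on the frame rate, because predictors are z-scored before model
fitting.

## Predictor selection

`pearson_matrix()` computes the 8-by-8 Pearson correlation matrix over
clips, and `correlation_blocks()` partitions the measures into connected
components of the graph with edges `|r| >= 0.5` (the threshold is a config
knob; 0.5 encodes "moderate to strong"). With real expression data this
typically yields a distance block and a speed/acceleration block;
`select_predictors()` then takes the mean-aggregated distance-to-neutral
and the mean-aggregated speed measure, one per block, avoiding collinear
predictor pairs. The aggregation policy (`mean` vs `max`) is switchable. No
multiplicity correction is applied to the exploratory matrix.

## Rating models

Ratings are visual-analog-scale integers in `[1, 101]`. Per clip and group,
arousal and valence are averaged over raters (`summarize_ratings()`); raters
are assigned to clips completely at random, so unequal rater counts induce
no bias in those means. The models are ordinary least squares on z-scored
predictors:

* **Within group:** `Arousal_G = b0_G + b1_G * Distance + b2_G * Speed + e`.
  Predictors are z-scored over exactly the analysis clips, so the intercept
  equals the group's mean rating. A fully standardized variant (response
  z-scored too) gives effect sizes; for a single predictor its slope equals
  the Pearson correlation, and the model's R-squared equals the squared
  standardized slope — identities the test suite checks exactly.
* **Between groups:** the per-clip difference of group means is regressed on
  the same predictors. A nonzero intercept is a mean rating offset between
  the groups; nonzero slopes would indicate group-dependent use of the
  kinematic cues.
* **Specificity:** both model families re-fit with valence as the response.

Confidence intervals are t-based at 95% by default. Leverage diagnostics use
the hat-matrix diagonal (`hat_values()`; mean exactly `k/n`).
`added_variable_data()` produces partial-residual pairs whose OLS slope
equals the full-model coefficient (Frisch–Waugh–Lovell), the standard way to
visualize a single coefficient. Because the reference analysis identified
extreme clips *visually* in such plots, the package formalizes flagging as a
configurable rule: clip `i` is flagged when its leave-one-out z-distance
`|x_i - mean(x_-i)| / sd(x_-i)` on the distance predictor exceeds 4. Flagged
clips are reported, never silently dropped; `refit_excluding()` re-fits on
the retained clips (re-z-scoring over the retained set, consistent with
z-scoring over the analysis set) and pairs original and re-fit coefficients.

## The synthetic-study generator

No landmark or rating data ship with the package; `make_study()` generates a
study with the statistical structure the analysis assumes, so every stage is
testable end to end and parameter recovery can be benchmarked.

**Clips.** A seeded face-like 68-landmark template (jaw, brows, nose, eyes,
mouth in the standard layout) is animated as
`frame_f = template + A * g(f) * field`, where `g` is a raised-cosine
envelope rising from 0 to 1 and back over `D <= T` frames (neutral → peak →
neutral) and `field` is a per-landmark direction pattern with unit RMS
length, made orthogonal to translation, scaling and rotation of the template.
Consequently:

* the amplitude `A` *is* the peak RMSD from the neutral face, and the
  noiseless distance series equals `A * g(f)` exactly (asserted to 1e-10);
* the mean of the discrete envelope over a full cycle is `(T-1)/(2T)`
  (0.495 at `T = 100`), so closed-form feature values exist for every clip;
* Procrustes normalization does not absorb the expression amplitude.

Optional per-coordinate tracking noise and per-frame similarity jitter
(translation/scale/rotation) emulate tracker output before normalization;
GPA removes the jitter up to the unit-size renormalization, which biases
measures by order `A` (a few percent at realistic amplitudes).

**Feature correlation.** Per-clip `(A, D)` are drawn jointly log-normal.
Distance scales with `A` times the envelope mass of `D` while speed scales
with `A`, so a target distance–speed correlation (default 0.51, the level
at which shared predictor variance becomes an issue worth studying) is hit
by solving for the latent log-scale correlation in closed form and
verifying the realized value, which the generator reports. The log-scale
spreads (0.30 for amplitude, 0.45 for duration) are fixed design constants
chosen as realistic relative variation in expression strength and tempo.
Amplitudes default to a median of 0.02 in consensus units, i.e. a peak
displacement around 16% of the per-landmark spread of the face — a clearly
visible but not extreme expression.

**Panels.** Arousal ratings follow the within-group linear model with
generative coefficients (47.60, 5.93, 2.53) on z-scored features, an ASD
intercept 4.29 points lower, a clip-level random effect (SD 18) shared by
both groups — per-clip rating deviations are properties of the videos, which
both groups watch — and rater-level noise (SD 25), rounded and truncated to
`[1, 101]`. The NT panel has 401 raters rating 1–6 clips each drawn from a
wider 125-clip stimulus pool of which 80 are analysed (≈11.2 raters per
analysed clip); the ASD panel has 19 raters rating 14 of the 80 clips each
(exactly 3.325 raters per clip). Valence is generated independently of the
kinematic features — the generator's default truth is that the predictors
are arousal-specific. Assignment is uniform without replacement per rater
(MCAR).

**What passing tests do and do not show.** The generator produces a
single-peaked, fixed-shape expression per clip. Real expressions have
multiple movement episodes, asymmetries, emotion-specific dynamics,
head-pose artifacts from out-of-plane rotation, and tracking failures; none
of these are emulated. One visible consequence: with only amplitude and
duration varying, the max-aggregated distance measure is proportional to
amplitude and therefore correlates strongly with the speed measures, so the
exploratory block structure of *synthetic* feature tables often collapses
into one block, unlike typical real data where static and dynamic blocks
separate. Tests passing on synthetic data validate the computational
machinery and the statistical calibration, not the empirical claims about
real faces.

## Benchmarking and problem sizes

`run_benchmark()` regenerates studies, re-fits the models, and reports
coverage of the generative truth. With 100 replicates of the default
80-clip design, 95% CIs for the distance coefficient cover the truth in
well over 88 replicates, difference-model slopes (truly zero) and valence
slopes (truly zero) cover zero in over 90, and the group offset estimate
falls within 2 standard errors of 4.29 in over 90. The within-2-SE event has
nominal probability just above 95%, so its count in 100 replicates
fluctuates around 95 — scale-rounding and truncation of the rating scale
shave a little off — which is why the suite's thresholds sit a few counts
below the nominal expectation rather than at it. The benchmark defaults to
closed-form features per replicate (benchmarking the rating-model stage);
`full_pipeline = TRUE` adds track generation, GPA and feature measurement to
every replicate. Test and benchmark problem sizes (80 clips, 100 frames, 100
replicates) match the design the defaults encode and run in well under a
minute each.

## Known limitations

* 2-D similarity alignment cannot correct perspective artifacts of
  out-of-plane head rotation; extreme distance values from turned heads are
  exactly what the outlier machinery is for.
* The eye region contributes 12 of 68 landmarks, upweighting eye state in
  all RMSD-based measures.
* Region-restricted measures (upper/lower face) and per-second units are
  out of scope; time is frames, and correlational conclusions are invariant
  to that choice.
* The outlier rule approximates a visual judgment; its threshold is a
  parameter, not a discovery procedure.
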