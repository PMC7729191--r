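# facekin

Kinematic predictors of arousal ratings from facial landmark tracking.

## What this package is for

When people watch a short video of a facial expression they can readily say
how *aroused* (calm vs. excited) the person looks — but which physical
properties of the moving face carry that judgment? facekin implements a
complete analysis pipeline for this question, aimed at affective-computing
and emotion-perception researchers working with automated face-tracking
output (OpenFace-style tables of 68 landmark positions per video frame):

1. **Normalization.** All frames of all clips are pooled into one
   Generalized Procrustes superimposition, removing position, size and
   rotation differences so that configurations from different clips are
   directly comparable.
2. **Kinematic measures.** For each clip, frame-wise series of

   - distance to a baseline face, as the root-mean-square deviation over
     landmarks, `RMSD(f, b) = sqrt( Σ_p d(p_f, p_b)² / N )`, against either
     the clip's first frame (*clip neutral face*) or the actor's
     per-coordinate average over all frames (*actor mean face*),
   - RMS speed between consecutive frames (time unit = one frame), and
   - RMS acceleration magnitude over two-frame windows,

   each aggregated by mean and maximum → eight measures per clip.
3. **Predictor selection.** The 8×8 Pearson correlation matrix over clips is
   split into blocks of `|r| ≥ 0.5`, and one representative is taken per
   block (by default: mean distance to the clip-neutral face, and mean
   speed) to avoid collinear predictors.
4. **Rating models.** Per-clip mean arousal ratings (visual-analog scale,
   integers 1–101) are modelled per rater group G by OLS on z-scored
   predictors,

   `Arousal_G = β0_G + β1_G·Distance + β2_G·Speed + ε`,

   plus a between-group model of the per-clip difference of group means
   (`Arousal_NT − Arousal_ASD = β0 + β1·Distance + β2·Speed + ε`), whose
   intercept measures a mean rating offset between groups. Standardized
   variants, t-based 95% CIs, leverage (hat) diagnostics, added-variable
   data (Frisch–Waugh), a configurable leave-one-out outlier rule with
   re-fits, single-predictor models, and valence-specificity re-fits are
   included.
5. **Synthetic studies.** A generator (`make_study()`) produces face-like
   landmark trajectories (neutral → peak → neutral raised-cosine envelope,
   amplitude = peak RMSD by construction) and NT/ASD rater panels whose
   ratings follow the within-group model with a known group offset — so the
   whole pipeline is testable and benchmarkable without any video data.

See the vignette (`vignettes/facial-kinematics.Rmd`) for the models,
assumptions, numerical choices and limitations in detail.

## Worked example

```r
library(facekin)

study    <- make_study(seed = 42)                      # 80 clips + NT/ASD panels
aligned  <- normalize_study(study$clip_set$tracks)     # pooled Procrustes frame
features <- compute_feature_table(aligned)             # 8 measures per clip

nt  <- summarize_ratings(study$ratings, "NT")
asd <- summarize_ratings(study$ratings, "ASD")

fit_within_group(features, nt)
fit_between_group(features, nt, asd)
```

```
Linear model: mean_arousal ~ dist_neutral_mean + speed_mean (NT)  (n = 80)
              term estimate         95% CI        p  std    std 95% CI
       (Intercept)    46.37 [42.63, 50.11] 2.65e-38 0.00 [-0.20, 0.20]
 dist_neutral_mean     6.41  [2.42, 10.40] 2.01e-03 0.34  [0.13, 0.55]
        speed_mean     4.63   [0.64, 8.62] 2.35e-02 0.24  [0.03, 0.46]
R2 = 0.23, adj. R2 = 0.21, residual SE = 16.81 (df = 77), F = 11.48 (df = 2; 77)

Linear model: mean_arousal difference (NT - ASD) ~ dist_neutral_mean + speed_mean  (n = 80)
              term estimate        95% CI        p  std    std 95% CI
       (Intercept)     6.38  [3.13, 9.63] 0.000199 0.00 [-0.22, 0.22]
 dist_neutral_mean     1.77 [-1.69, 5.24] 0.312000 0.12 [-0.12, 0.36]
        speed_mean     0.47 [-2.99, 3.94] 0.786000 0.03 [-0.21, 0.27]
R2 = 0.02, adj. R2 = -0.01, residual SE = 14.60 (df = 77), F = 0.73 (df = 2; 77)
```

Reading the output: in the NT model, one standard deviation more distance to
the neutral face predicts a 6.41-point higher mean arousal rating (95% CI
[2.42, 10.40]) at constant speed. In the difference model only the intercept
is significant: the ASD panel rates clips lower on average (estimate 6.38;
this study was generated with a true offset of 4.29, which the CI covers),
with no evidence that the groups use the kinematic cues differently — the
structure the generator encodes. `run_study1()` / `run_study2()` wrap these
steps with artifact export, and `inst/scripts/facekin.R` exposes them as a
command line (`simulate`, `study1`, `study2`, `benchmark` subcommands).

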