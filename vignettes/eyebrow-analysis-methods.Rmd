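---
title: "Methods: quantifying eyebrow prosody from pose-estimation keypoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying eyebrow prosody from pose-estimation keypoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(browprosody)
```

## The scientific problem

In sign languages the face carries both grammar and affect through the same
articulators. Polar (yes/no) questions are typically marked by raised
eyebrows; surprise raises them too (AU1 + AU2 in FACS terms), while anger
lowers the inner brow (AU4). When a signer produces an angry polar question,
the two systems compete. This package implements a quantitative pipeline for
studying that competition: it measures average eyebrow position per short
video from automatically tracked facial landmarks and asks how emotion
(neutral / anger / surprise), sentence type (statement / polar / wh) and
signer group (deaf / hearing native signers) jointly shape it.

The design it targets is a fully crossed production study: 9 signers (5
deaf, 4 hearing) x 10 sentences x 9 conditions = 810 videos, processed at
30 fps by a pose-estimation system that emits, per frame, 70 facial
landmarks plus hand and body keypoints, each with an (x, y, confidence)
triplet.

## From keypoints to two numbers per video

1. **Confidence filter.** Every landmark with detection confidence strictly
   below 0.7 is treated as undetected; a point at exactly 0.7 is kept. The
   filter is idempotent and applied before any geometry.
2. **Nose-relative distance.** Raw y-coordinates confound eyebrow movement
   with body and head position, so eyebrow height is the Euclidean distance
   (x and y jointly) from the nose-top landmark (face index 27). "Distance
   using both coordinates" admits a signed-vertical reading; we implement
   the Euclidean one and note that for near-vertical inner-brow geometry the
   two differ only at second order.
3. **Edge trim.** The first and last `floor(0.2 * n)` frames are dropped by
   position. Signers raise their hands into signing space at the start and
   retract them at the end; those spans are not part of the utterance. The
   fraction is a fixed constant of the configuration, not auto-detected:
   `hand_activity_profile()` exists to *inspect* wrist elevation against the
   trim, not to set it. `floor()` makes retained counts exactly
   reproducible and never removes more than 40% of frames.
4. **Internal / external averaging.** Per frame, the internal measure is the
   mean distance of inner-brow points 21 and 22, the external of outer
   points 18 and 25 — averaging over the two eyebrows because faces are not
   symmetric. With the default `require_both_sides = TRUE`, a frame
   contributes a measure only if both sides (and the nose) survived the
   filter; one-sided availability would otherwise leak asymmetry into the
   mean. The left-minus-right asymmetries are computed as diagnostics but
   not modelled.
5. **Per-video mean.** The analysis deliberately ignores within-video
   dynamics and averages each measure over the retained frames. A video
   with no surviving frames for either measure is dropped; under the
   default generator this reproduces an 805-of-810 yield.

Units are raw pixels throughout: the recording setup (fixed camera, seated
signer) makes them comparable across videos, and an inter-ocular
normalization flag exists for sensitivity analysis but defaults off.

## The mixed-effects model

Each outcome (internal, external) is fitted separately — the notation
"internal/external ~ ..." is read as two univariate fits with identical
right-hand sides:

```
outcome ~ emotion * sentence_type * group +
          (emotion * group | sentence_id) +
          (emotion * sentence_type | signer_id)
```

Factors are comparison-coded so every coefficient is a named pixel
difference: `NvA` = neutral − anger, `SvNA` = surprise − mean(neutral,
anger), `WvS` = wh − statement, `PvSW` = polar − mean(statement, wh), and
group `DvH` = deaf − hearing (±1/2 coding). The fixed design has 18
columns; the by-sentence random block is 6-dimensional and the by-signer
block 9-dimensional.

**Covariance regularization.** With 9 signers and 10 sentences, REML
estimates of 6- and 9-dimensional random-effect covariances routinely hit
the singular boundary. We therefore maximise a penalized REML criterion
built with lme4's modular API: the objective is the REML deviance minus the
log-density of an improper Wishart prior (`nu = p + 2.5`, infinite scale)
on each covariance block, which reduces to `-3 * sum(log diag(Lambda))` on
the relative covariance factor. The penalty diverges at the boundary, so a
singular estimate is impossible by construction, while away from the
boundary it is weak (it adds 3 log-units per dimension to a deviance
typically in the thousands). The degrees-of-freedom offset 2.5 is the
conventional default of this prior family; no data-dependent tuning is
involved. Optimization uses bounded BOBYQA (`lme4::nloptwrap`) from the
standard starting point (identity relative covariance).

If the optimizer fails outright, the random structure is simplified in a
fixed, logged order: drop the by-signer interaction slopes, then the
by-sentence interaction slopes, then all slopes. Each fit records
`converged`, `singular` and the structure actually used.

**Inference.** Term-level tests are Wald chi-square (`car::Anova`), Type II
by default (Type III available); degrees of freedom are the contrast counts
(2, 2, 1, 4, 2, 2, 4). p-values use the chi-square reference distribution
with no small-sample correction, matching the Wald reporting convention.
Estimates are reported in pixels with standard errors and t values;
positive means higher eyebrows for the first-named side of the contrast.

## What the synthetic generator emulates

`generate_study()` produces the full crossed design with analytic ground
truth. At the **keypoint level** it renders a schematic 70-point face on a
1280x720 canvas with the nose top fixed; eyebrow landmarks sit at their
baseline distance (defaults: 45 px internal, 75 px external) and are
displaced *radially* from the nose top, so a displacement of d changes the
measured distance by exactly d and the expected per-video summary is an
exact linear function of the injected effects. Each video adds:

- fixed condition effects injected in the same contrast space the model
  estimates (defaults are the estimates a production study of this design
  reports: internal 3.7, 4.0, 0.3, 2.3 px for the four main contrasts with
  a −1.8 px polar x group interaction; external 0.45, 2.5, 0.09, 2.5 px
  with −2.0 surprise x wh, −1.8 wh x group, −2.3 polar x group and +3.3
  surprise x wh x group interactions; the three-way sign is our convention,
  as prose reports magnitude only);
- by-signer and by-sentence random intercepts (sd 3 and 2 px) and slopes
  (40% of the intercept sd) — values chosen so that fitted standard errors
  are of the order reported for this design (0.3–1.1 px); the source
  analysis publishes no variance components, so these are free parameters
  of the emulation, documented here once;
- iid Gaussian frame noise (sd 3 px) on every landmark coordinate;
- confidence dropouts: each keypoint falls below the 0.7 cutoff with
  probability 0.05, with confidences drawn from a high beta mass otherwise;
- a −5 px eyebrow perturbation and a triangular wrist-elevation bump
  confined to the first and last 20% of frames, so edge trimming measurably
  matters and the hand diagnostic shows activity exactly where the trim
  removes it (a deliberate simplification: real preparation movements pass
  *through* intermediate heights rather than bumping at the edges);
- 5 videos (configurable) rendered with all confidences below the cutoff,
  reproducing the dropped-video phenomenon.

The **summary level** draws per-video means directly from the identical
linear model, with residual sd `sd_frame * sqrt(1.5 / n_eff)` — the
analytic consequence of averaging `n_eff` retained frames whose
internal/external value carries variance `1.5 * sd_frame^2` (two brow
points averaged plus a shared nose point). Simulation studies (parameter
recovery over 20 replicates, type-I error over 200) use this level; the
keypoint renderer is verified against the analytic ground truth exactly in
the noiseless limit and at full 810-video scale once per run. These problem
sizes keep a complete verification run in minutes while leaving the
recovery standard errors small relative to the 2-SE criterion.

What the generator does **not** emulate — and hence what passing tests do
not establish about real recordings: head rotation and translation,
correlated (non-iid) tracking error, systematic confidence loss during fast
movement, within-sentence prosodic contours, and any photometric realism.
The pipeline's robustness to those belongs to validation on real data, not
to this test bed.

## Numerical and design choices

- **Threshold boundary:** strictly-below 0.7 removed, exactly-0.7 kept.
- **Trim rounding:** `floor` at each end, positional.
- **Distance:** Euclidean; zero when brow and nose coincide.
- **Missing sides:** both required per measure by default (configurable).
- **Degenerate inputs:** an empty frame directory, a one-signer table or an
  all-missing outcome raise immediate input errors; videos losing all
  frames become `dropped` rows, not errors.
- **Ties/order:** frame files sort by their parsed integer index, so
  shuffled listings and unpadded names are safe.
- **Kappa edge case:** two identical constant raters give kappa 1 by
  definition (the formula is 0/0 there) with a logged note.
- **Chance-corrected accuracy** is reported for both 3 and 4 answer
  options, since "other" is an available response but never a correct one;
  whether below-0.7-confidence responses should be excluded does not arise
  here, and the denominator always includes "other" responses.
- **Separate univariate fits:** internal and external could be modelled
  jointly; the univariate route matches the reporting structure the design
  targets and keeps the covariance penalty block-diagonal.

## Known limitations

The covariance penalty guarantees non-singularity but, like any shrinkage,
biases small variance components upward; variance components are therefore
reported for inspection, not tested. Wald chi-square tests ignore
uncertainty in the random-effect estimates and can be mildly anticonservative
with few grouping levels — the type-I simulation in the acceptance suite
bounds this empirically at the sizes used. The asymmetry features are
extracted but unmodelled. Pose input accepts both 24- and 25-point body
layouts without resolving which produced a given file.
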