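---
title: "dyadkin: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dyadkin: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents how `dyadkin` defines its quantities, which
conventions were open design choices, and what the synthetic data do and do
not establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Data model and conventions

A *scene* is one 4-s dyadic interaction: two agents, each a
`frames x 15 x 3` trajectory array in millimetres at `fps` Hz (default 400
frames at 100 Hz). Axes are x, y horizontal and z vertical (up-positive);
this convention is load-bearing for vertical movement, symmetry and the
facing test, and the scene I/O preserves it end-to-end. Frames are indexed
0-based on disk and 1-based in R; `fps` is always stored, never assumed.
Feature extraction uses the 13 *anatomical* markers (head, shoulders,
elbows, wrists, hips, knees, ankles), excluding sternum and sacrum.

The canonical on-disk format is a long CSV (`frame,agent,marker,x,y,z`)
plus a JSON manifest for datasets. C3D is accepted in the interface
signature but raises an informative error: no C3D reader exists in the
supported dependency set, and the tabular dialect carries the full
contract, so the test suite runs with no binary dependency. Interior runs
of missing samples up to `max_gap` frames (default 5) are linearly
interpolated at read time; longer or edge gaps are errors. Motion-capture
pipelines need *some* gap policy and linear interpolation is the least
committal choice at 100 Hz.

## Intrapersonal features

* **VEL** — per-marker forward-difference speed (mm/s), averaged over
  steps, markers and agents. **ACC** is the absolute forward difference of
  the *speed* series (derivative of speed, mm/s²), not the magnitude of the
  vector acceleration; the derivative-of-speed reading is the simplest one
  consistent with "derived from velocity" and is what the implementation
  commits to.
* **VM** — cumulative |Δz| path per marker over the whole clip, averaged
  over markers and agents. The cumulative (not per-step-mean) reading is
  the only one that produces hundreds of millimetres over a 4-s clip, the
  magnitude the feature is reported in.
* **VOL / VOL_STD** — per-frame bounding-box volume (m³) and its SD.
  Deliberate deviation from a literal world-axis box: extents are taken
  along the agent's *body axes* (the horizontal left-right axis estimated
  from the shoulder and hip lines, its horizontal perpendicular, and the
  vertical). A world-axis box is not invariant under rotation of the scene
  about z, which the package's invariance suite (and any sane rigid-motion
  requirement) demands; the body-aligned box is, while keeping the same
  magnitudes. Degenerate left-right axes fall back to world axes.
* **SM** — asymmetry score. Midline = the vertical sagittal plane through
  the midpoints of the hip pair and the shoulder pair, with the horizontal
  left-right axis as its normal. Per frame and left/right pair, three
  components: height difference |z_L − z_R|, difference of perpendicular
  distances to the plane, and the angular offset of the pair's chord from
  the plane normal expressed as an *arc length at half the chord*. The
  arc-length form puts all three components in mm, so the default scalar is
  their equal-weight mean and scales linearly under uniform spatial
  scaling, exactly as the invariance suite requires. A collection-level
  z-scored aggregation (which removes the unit question by standardising
  across scenes instead) is available via `scale_symmetry_components()`;
  it was not made the default because it leaves a single scene's feature
  undefined and breaks scale homogeneity. The composite is isolated behind
  one function with a documented contract, as its exact published
  composition is ambiguous.
* **LA** — mean interior angle (degrees) over 8 joints: shoulder
  ∠(elbow, hip), elbow ∠(shoulder, wrist), hip ∠(shoulder, knee), knee
  ∠(hip, ankle), left and right.
* **LC** — mean head↔{wrists, ankles} distance (mm); larger = more
  extended.

All per-agent scalars are arithmetically averaged over the two agents, with
no body-size weighting; VOL_STD averages the per-agent SDs.

## Interpersonal features

Agent centroids are the mean of the 13 anatomical markers — more robust
than a single sacrum marker and consistent with the marker-exclusion rule.

* **IPD / IPD_STD** — time mean and SD of the per-frame centroid distance.
* **PS** — percent of frames with centroid separation below one arm length.
  The arm length is *estimated from the scene* (time-mean shoulder→elbow +
  elbow→wrist, averaged over arms and agents) rather than fixed; whose arm
  is unspecified in the source description, so the two-agent mean is used.
  A minimum-marker-distance variant sits behind `min_marker = TRUE`.
* **IPO / IPO_BAL** — "facing" is an open definition; the package commits
  to: the horizontal outward normal of the shoulder line (front
  disambiguated by the horizontal head offset) within a 45° half-angle cone
  (configurable) of the horizontal direction to the partner's centroid.
  IPO is the mean of the two agents' facing percentages, which equals
  mutual facing plus half of each one-sided share; a strict-mutual mode is
  available. Balance is reported as `1 − |t₁ − t₂|/(t₁ + t₂)` so that
  *higher = more balanced*: the literal difference-over-sum formula
  contradicts its own gloss, and the gloss wins. The same sign convention
  applies to ME_BAL. `IPO_BAL` is defined as 0 when neither agent ever
  faces.
* **DC_*** — Pearson correlations between the per-frame distance profile
  and the *agent-averaged* per-frame profile of VEL/ACC/VOL/LC
  ("whole-body movements" reads as dyad-level, not per-agent-then-average);
  differenced profiles are aligned by truncating the distance profile.
  Zero-variance profiles yield NA with a warning, and NAs are excluded or
  median-imputed downstream rather than silently zeroed.
* **SYNC_VEL / SYNC_ACC** — zero-lag Pearson correlation between the two
  agents' speed (speed-derivative) profiles. Windowed or lagged synchrony
  is out of scope by design.
* **ME_BAL** — `1 − |E₁ − E₂|/(E₁ + E₂)` with `E_i` the summed mean-marker
  displacement of agent i; 0 when the dyad is static.

Correlation-valued features are Fisher-Z transformed (`atanh`) before the
ANOVAs, always — normality screening is not automated. Post hoc tests are
pair-wise pooled-variance t tests, Bonferroni-corrected by the number of
pairs, with a Welch variant behind a flag.

## Synthetic scenes: the stated world

The generator emulates the *statistical structure the analysis assumes*,
not biomechanics. Each agent is a fixed 15-marker template (generic adult
segment lengths: arm ≈ 550 mm, shoulder width ≈ 380 mm; configurable
implicitly through the pose interpolation) posed between a contracted and
an extended posture by `posture_openness`, then animated by three
superposed processes:

1. a root path implementing the linear `start_ipd → end_ipd` separation
   schedule plus a small smooth wobble, lateral wander and a 1.1-Hz
   vertical bounce of amplitude `bounce_amp`;
2. a yaw schedule that keeps each agent oriented toward the partner for a
   programmed fraction of the clip, with smooth 60–100° aversions
   otherwise;
3. smooth per-marker noise whose per-step magnitude is an envelope times a
   per-marker amplitude. The global amplitude is solved by bisection so the
   realised mean marker speed *equals* `speed_scale` (agent 2:
   `energy_ratio · speed_scale`), which pins both VEL and ME_BAL; the two
   envelopes are linear mixtures of smooth latents residualised so their
   sample correlation equals `sync_level` exactly, which pins SYNC_VEL up
   to rare clipping. A small deformation floor keeps posture profiles
   non-degenerate when root motion alone already exceeds a slow speed
   target (the realised speed then overshoots the target; the archetype
   contrasts survive).

One field extends the archetype parameter list beyond the obvious set:
`facing_balance`, the ratio of agent 2's to agent 1's facing time. Without
it both agents face equally long and the orientation-balance feature is
constant ≈ 1 across all emotions, so the affection-maximal balance contrast
the acceptance suite requires could not exist in the generated world.

Default archetypes (speed 374/205/124/335 mm/s, bounce 40/12/8/25 mm,
separation schedules ~1.0 m/0.5 m/0.9 m/1.2 m, facing fractions
0.40/0.80/0.32/0.25, energy ratios 0.87/0.82/0.64/0.61 for
happiness/affection/sadness/anger) were calibrated once against the
extractor so the qualitative cross-emotion orderings — fastest and
bounciest happiness, closest and most mutually oriented affection, slowest
sadness, most distant and least balanced anger — are reproduced; exact
group means are explicitly *not* targets, since they depend on an
unreleased corpus. Dataset generation jitters each scene's parameters
(relative SD 0.08, bounded parameters clipped) and derives one child seed
per scene from the master seed; identical seeds give bit-identical
datasets.

Simulated raters draw emotion responses from a 4×4 confusion matrix (rows ≈
0.91/0.80/0.88/0.92 on the diagonal, affection→happiness the most common
confusion, anger↔happiness the rarest) and integer valence ratings from
per-emotion Gaussians (means +3.5/+3/−2.5/−3.5, SD 1.2), rounded and
clipped to −5..+5. Per-stimulus rating structure beyond this is left as
free configuration — the aggregate-level behaviour is all the analysis
consumes.

**What a green test does not establish:** the generator's filtered-noise
kinematics have no gait, contact or torque realism; marker trajectories are
smooth where real mocap has sensor noise and occlusion artefacts; the
rater model has no per-scene difficulty, order effects or rater biases.
Green tests establish that the *pipeline* recovers programmed structure,
not that the archetypes describe human emotion expression.

## Classifier

Plain bagging (no per-split feature subsampling): 200 unpruned CART trees
by default (the source description names no ensemble size; 200 makes the
importance shares stable at 48 scenes), Gini impurity, splits at midpoints
between distinct values, random tie-breaking among equal-gain predictors
under the ensemble seed. Prediction is a plain majority vote with a
deterministic first-class tie-break; a score-weighted vote was considered
("weighted majority" is undefined in the source) and left out as the less
parsimonious reading. Importance is node-weighted impurity decrease summed
over splits and trees, normalised to sum 1. Cross-validation is balanced
leave-one-per-category: fold k tests the k-th scene of every emotion, so
folds partition the data and training stays balanced; missing
correlation-valued predictors are imputed with the *training fold's*
medians, keeping folds valid without test leakage. At very small training
sizes (≲ 3 scenes per class) many predictors tie at the maximal single
split gain and random tie-breaking dilutes accuracy — an inherent property
of exhaustive trees, visible in the unit tests, irrelevant at the default
12 scenes per class.

## Representational similarity analysis

All RDMs are validated on construction (symmetric, zero diagonal,
nonnegative). Kendall's τ_A divides concordant-minus-discordant by the
*total* number of entry pairs (ties uncounted in the numerator only) — the
convention appropriate for comparing RDMs with tied entries; note
τ_A(x, x) < 1 whenever x has ties, which is why only tie-free constructions
can attain a ceiling of exactly 1. The implementation uses an
O(m log m) grouped count when either vector has few distinct values (the
binary behavioural RDMs) and a τ_b-to-τ_A conversion otherwise; both paths
are checked against brute-force pair enumeration.

Open choices committed to:

* model-vs-feature significance: two-sided scene-label permutation test
  (default 10,000 permutations, seeded; tests and the acceptance script
  pass smaller counts for runtime, which only coarsens the p resolution);
  Bonferroni by the feature-set size.
* behavioural emotion RDMs follow the methods-text definition (0 if the
  two scenes received the same response, 1 otherwise) rather than the
  correct/incorrect coding that appears in one figure caption; group-mean
  RDMs are entrywise means of the binary per-rater RDMs.
* noise ceiling: the standard two-bound estimator — upper = mean
  correlation of each rater's RDM with the group mean including that rater,
  lower = with the leave-one-out mean; both bounds are reported since the
  exact estimator is not spelled out in the source description.
* combination RDMs min-max normalise each upper triangle to [0, 1] before
  entrywise averaging ("normalising the representational geometry" admits
  several readings; z-scoring sits behind a flag).
* MDS is classical (Torgerson) on the 1 − τ_A distances; no iterative
  refinement, hence no extra seed.
* feature-vs-behaviour inference: one-sided Wilcoxon signed-rank across
  raters per feature (Holm-corrected, BH-FDR flags at 0.05), two-sided
  signed-rank for feature pairs with BH control; all-zero difference
  vectors return p = 1 by convention.

## Numerical and degenerate-input policy

Round-trips hold to 1e-6 mm (the writer emits 15 significant digits);
oracle-equivalence tests run at 1e-9 relative tolerance; |r| ≥ 1 is clipped
inside the open interval before `atanh` with a warning; zero-variance
profiles, constant features and constant RDMs degrade to NA/warnings, never
silent zeros; a collapsed body midline or coincident shoulder markers are
hard errors naming the frame. All randomness flows through explicit seeds;
`run_all()` fans one master seed into per-stage child seeds so stages can
be re-run in isolation, and re-running a saved config reproduces every CSV
byte-for-byte (fixed-precision writers).

## Known limitations

* No C3D ingestion in this build (see above).
* The synthetic world cannot, by construction, validate absolute feature
  magnitudes against real interactions — only orderings, invariances and
  pipeline correctness.
* Zero-lag correlations only; no lagged synchrony or recurrence measures.
* The symmetry composite's published composition is ambiguous; the
  arc-length construction here is one defensible reading, flagged at the
  function level.
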