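---
title: "Methods: simulating and decoding navigationally relevant fMRI responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding navigationally relevant fMRI responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navaff)
```

## The design

Ten conditions cross a navigational-affordance factor with an ego-motion
factor. Conditions 1–6 depict translation through a room with an open
doorway on the left (2, 5), the right (3, 6), or both sides (1, 4), moving
forward (1–3) or backward (4–6). Conditions 7–10 depict turns: toward the
doorway ("consistent", 7 and 10) or toward the painting on the opposite
wall ("inconsistent", 8 and 9). `condition_table()` is the single source of
this mapping for every module.

Stimuli last 2.5 s and are separated by inter-stimulus intervals drawn
uniformly from [3.5, 9.5] s. Each of 8 runs contains 4 repetitions per
condition (40 events, 32 repetitions per condition over the experiment) in
228 volumes at TR 2 s (456 s, 7:36). The category localizer is a 315 s
block design — 21 blocks of 15 s (5 clips of 2.8 s + 0.2 s ISI), four
stimulus blocks per category plus five fixation blocks, alternating block
sets palindromic — acquired over 158 volumes (316 s, 5:16). The fixation
blocks are taken to be 15 s like the stimulus blocks; only that choice
makes the 21-block structure span exactly 315 s, so the localizer is
reproduced here as a timing check rather than a modeled stage.

ISI jitter is sampled uniformly within the stated bounds rather than
optimized: schedule optimization tunes estimator efficiency, not validity,
and uniform jitter preserves the design's timing constraints. If a draw
would overrun the run, only the jitter *above* the minimum ISI is shrunk,
so the bounds are never violated; packings that cannot fit even at the
minimum ISI raise an error. Room textures (8 types) are assigned by a
seeded cyclic rotation per condition, which makes per-condition room counts
exact (or within ±1 when counts do not divide) and keeps a condition's
repetitions within a run in distinct rooms.

## The generative model

`simulate_betas()` draws, for each subject × ROI × hemisphere × run, a
voxels × conditions amplitude matrix

```
beta[v, c] = baseline
           + affordance_contra * [doorway contralateral, conditions 1–6]
           + forward_bias      * [forward motion]
           + turn_contra_bias  * [turn toward the contralateral hemifield]
           + consistency_gain  * [consistent contralateral turn]
           + ego_motion_code   * U[v, ego(c)]
           + subject offset z[v]  (SD noise_sd_subject)
           + run noise            (SD noise_sd_run)
```

with `U` a per-hemisphere standard-normal pattern over voxels for each
ego-motion direction. All effect magnitudes are in units of the run-noise
SD. The lateralization follows the retinotopic organization of visual
cortex: a doorway on the left of the scene falls in the left visual
hemifield and boosts the *right* hemisphere (and vice versa); both-door
conditions are boosted bilaterally; the right hemisphere's contralateral
turns are the left turns.

Two modeling choices deserve justification:

- **The doorway boost applies to the translation conditions (1–6) only.**
  During turns the doorway sweeps across the visual field, and empirically
  the door-vs-painting preference does not express within turn conditions
  (the ipsilateral consistent-vs-inconsistent contrast sits at zero).
  Injecting the boost on turns would force a negative ipsilateral
  consistency difference, contradicting that observed pattern. The turn
  conditions instead carry `turn_contra_bias` and, on the consistent
  contralateral turn only, `consistency_gain` — an interaction term, which
  is what makes the consistency effect contralateral-specific downstream.
- **Noise is white at both levels.** Run noise is i.i.d. Gaussian per
  voxel × condition; BOLD noise (level `"bold"`) is white over volumes.
  The estimator is plain OLS, so the simulated noise matches its
  assumption; temporal autocorrelation modeling (prewhitening) is out of
  scope and would change nothing about the logic being tested.

Effect-size defaults (1 SD for `affordance_contra`, `ego_motion_code`,
`turn_contra_bias`, `consistency_gain`; 0.5 for `forward_bias` and
`room_texture_code`; `noise_sd_subject = 0.5`) describe a signal-rich demo
world in which every pipeline stage has recoverable structure. They are
deliberately *not* calibrated to reproduce any particular empirical effect
size: real fMRI effects of this kind are far noisier, and nothing here
should be read as a claim about power in real data.

What the generator does **not** emulate: physiological drift and motion
artifacts, spatial voxel correlations, temporal autocorrelation,
between-region differences in signal quality (unless set via `roi_gain`),
and the visual stimuli themselves. Tests passing on this generator
therefore validate the *analysis machinery* — estimator correctness,
calibration of the group tests, recovery and specificity of each injected
effect — not the neuroscientific conclusions one could draw from real
data.

## GLM

Task regressors are per-event boxcars convolved with the canonical
double-gamma HRF (delays 6/16 s, dispersions 1/1, undershoot ratio 6,
peak-normalized) on a grid oversampled 10× relative to the TR — onsets are
jittered, not TR-locked — then decimated to volume times. The printed
high-pass specification "120 Hz" is physically meaningless at TR 2 s and is
read as a 120 s cutoff *period*, consistent with the 128 s-class cutoffs
standard for event-related designs. Drift is an orthonormal DCT block of
order `floor(2·n·TR/cutoff + 1)` (constant included); `highpass()` projects
the same subspace out of data, so filtering data and design is exactly
equivalent to including the drift columns as regressors (a Frisch–Waugh
identity the tests verify). Estimation is per-run OLS via QR; rank
deficiency is an error that names the collinear columns.

## Split-half cross-validated distances

For a subject with `n` usable runs, every unordered partition into halves
of `floor(n/2)` vs `ceiling(n/2)` runs is a fold (35 folds for 8 runs; 10
2-vs-3 folds for 5). Within a fold, each condition's mean pattern (both
hemispheres' voxels concatenated) is computed in each half, and entry
(i, j) of the distance matrix is the Euclidean distance between condition
i's pattern in one half and condition j's in the other — including i = j,
whose distance is positive under noise and serves as the "within" baseline.
Because "the other half" is a direction, each fold's matrix is symmetrized
over orientation, `(d_AB + d_BA)/2`, making results invariant to half
labeling. Fold matrices are averaged element-wise. Distances are raw
Euclidean — no pattern normalization or noise whitening — so they carry
both spatial-pattern and overall-activation information; that is a feature
of the measure, not an omission.

A hypothesis matrix labels every ordered condition pair `within`,
`between`, or `excluded`; the decoding score is the unweighted mean of
between-labeled cells minus the mean of within-labeled cells (self-pairs
count as within; groups contribute cells, not group means). The six
schemes:

| scheme | conditions | within | between |
|---|---|---|---|
| `affordance_overall` | 1–6 | same doorway side (+self) | all other pairs |
| `affordance_generalize` | 1–6, cross-motion pairs only | same side | different side |
| `egomotion_overall` | all 10 | same direction (+self) | forward–backward, left–right turns |
| `egomotion_generalize` | as overall, pairs differing in doorway side | same direction | matched different directions |
| `conflict` | 7–10 | same consistency (+self) | consistent–inconsistent |
| `room_texture` | 8 room types | same room (self across halves) | different rooms |

Turns are excluded from the affordance schemes because a turn changes the
doorway's hemifield within the trial. The generalization schemes are
strict subsets of their overall counterparts (a tested invariant). For
`egomotion_generalize`, *both* within and between pairs must differ in
doorway side; self-pairs drop out automatically. Room-texture decoding
runs on room-resolved patterns — the run-level regressors group events by
room type instead of condition (`by = "room"`), giving 8 patterns per run —
and its hypothesis matrix is simply same-room (the cross-split diagonal)
vs different-room, the most direct formalization of "more similar patterns
for the same room texture".

## Univariate contrasts

ROI responses average voxels within each run first and runs second (the
order matters for unbalanced run counts). Hemisphere-resolved contrasts
compute each hemisphere's contralateral and ipsilateral values first and
then average the two hemispheres unweighted. The four contrasts —
contralateral doors vs paintings (conditions 2/5 vs 3/6 by hemisphere),
forward vs backward (whole-field, 1–3 vs 4–6, both-door and single-door
conditions weighted equally), contralateral vs ipsilateral turns, and
consistent vs inconsistent turns split by visual field — are each invariant
to global offsets, equivariant to positive scaling, and invariant to
mirror-relabeling of hemispheres and sides (tested properties).

## Group inference

Group tests are paired t-tests; decoding tests are one-tailed toward
positive difference scores. Two-way repeated-measures ANOVAs (e.g., 3
regions × within/between) are computed by projecting each subject's cell
vector onto orthonormal Helmert contrasts per effect; the
Greenhouse–Geisser epsilon comes from the covariance of those contrast
scores, `ε = tr(Σ)² / (d·tr(Σ²))`, and corrected p-values use the
ε-deflated df on both sides. Both corrected and uncorrected results are
always reported, since published ANOVAs of this kind mix the two formats
and the selection rule is rarely stated. One caveat the tests made
explicit: the folk claim "the GG-corrected p is never smaller than the
uncorrected p" holds in the reporting regime (F ≥ 1) but is false for
sub-unity F, where deflating both dfs can shrink the upper tail; the
package reports the standard computation unconditionally. A post hoc 2×2
interaction contrast is the same ANOVA restricted to two levels per
factor, where F equals the squared paired t on the per-subject double
difference. Power for the paired design uses the exact noncentral t
(df `n−1`, noncentrality `d√n`); with n = 16 and two-tailed α = .05 it
gives 84.8% for d = 0.8 and 96.8% for d = 1.02 — the planned 85% / 97%.

Subjects missing an ROI are dropped listwise from analyses involving it,
so degrees of freedom follow the data. Usable-run scenarios (8/6/5 runs in
a 12/1/3 mixture over 16 subjects by default) restrict every downstream
stage to the usable runs; subjects with fewer than two usable runs are
rejected because the split-half analysis is undefined.

## Numerical and calibration choices

- Seeds: every stochastic operation derives its own stream from the config
  seed (multiplicative-congruential mixing, always below 2³¹), so outputs
  are bit-reproducible piecewise and the caller's RNG state is untouched.
- ROI selection ties at the cut break toward the lowest voxel id —
  deterministic and seed-free.
- Degenerate ANOVA cells: an effect with zero sum of squares reports F = 0
  (covers noiseless additive data where the error term is also zero);
  a zero-covariance contrast space reports ε = 1.
- Squared distances are clamped at zero before the square root to absorb
  negative round-off.
- Calibration problem sizes: the null-calibration suite uses 2000 simulated
  16-subject experiments (one ROI, 8 runs, 50 voxels per hemisphere) and
  the recovery suite 200; the acceptance script reports scaled-down
  re-runs (500 and 100) plus one full-scale demo pipeline. These sizes give
  Monte-Carlo SEs comfortably inside the tested bands (e.g. ±0.005 on a
  0.05 rejection rate at n = 2000).

## Known limitations

Real-data ingestion is limited to the documented tabular adapter (events
TSV plus per-run beta tables); the package does not preprocess raw BOLD.
Correlation or Mahalanobis distances, searchlight mapping, and
classifier-based decoding are deliberately out of scope, as are voxelwise
whole-brain maps. The localizer is simulated at the category-mean level
only — sufficient for selection logic and provenance guarantees, not a
block-design GLM.
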