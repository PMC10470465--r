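---
title: "rigid4d: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rigid4d: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rigid4d)
```

## The scientific problem

When a rigid three-dimensional object is projected onto the retina, one
dimension is lost, and the projected image is generically *not* rigid: image
distances between feature points change as the object rotates. The visual
system nevertheless judges the rigidity of the original object, which
requires reconstructing structure in the native dimension. The same logic
extends one dimension up: a rigid four-dimensional object (a hypercube,
16 vertices and 32 edges) projected into 3D yields a non-rigid 3D wireframe,
so an observer who can reliably tell rigid from non-rigid *4D* motion must be
extracting four-dimensional structure. `rigid4d` implements the full
experimental pipeline around that logic — stimulus geometry and motion,
projection, two-alternative forced-choice (2AFC) sessions, a synthetic
observer, and the statistical analysis — so that every stage is testable
without human subjects.

## Stimulus model

### Geometry

`make_hypercube(d, side)` builds the regular wireframe: vertices at all sign
combinations of `side/2` (so `2^d` vertices), edges joining Hamming-distance-1
pairs (`d * 2^(d-1)` edges). The stimuli use `side = 100` cm, `d = 3` (8/12)
and `d = 4` (16/32).

Irregular ("distorted") objects displace every vertex by an exact distance of
`level * side` — 12, 18 or 24 cm at the three irregularity levels — in a
uniformly random direction, drawn by normalizing standard-normal vectors
(exactly uniform on the sphere). For 4D objects the displacement acts on the
(x, y, z) components only, leaving w untouched: the positional shifts operate
at the three-dimensional level, which is what breaks the interspatial
relations of the hypercube under 4D motion. Whether the original experiment
perturbed before or after the 4D-to-3D projection is not stated in the source
material; we perturb *pre-projection* on the first three coordinates (the
natural reading, and the variant that keeps the 4D object well defined), and
expose `space = "full"` for full-4D displacement as a sensitivity switch.

### Motion

Rigid motion is a composition of oscillating plane rotations. In d
dimensions a simple rotation leaves a `(d-2)`-dimensional subspace pointwise
fixed; in 3D that is the familiar axis, in 4D it is a *plane*. We name
rotations by their invariant coordinates: the named plane (e.g. x–y) stays
fixed and the complementary pair (z–w) rotates. This is one of two possible
readings of naming a rotation "along" a plane; the opposite convention is a
constructor switch (`plane_convention = "rotating"`). Each plane's angle
follows

θ_i(t) = A_i · sin(2π f_i t + φ_i),

an oscillation over a fixed angular range (a triangular wave is available via
`angle_schedule`). Defaults: A = 30°, f = 0.25 Hz — ±30° sweeps completing
three quarters of a cycle over the 3 s presentation, visible but not
disorienting. 3D objects rotate about x and y; 4D objects compose all three
of the y–z, x–z and x–y invariant-plane rotations simultaneously with
staggered phases (0, π/3, 2π/3) so the three angles are never phase-locked.
The exact amplitudes, frequencies and phases of the original stimuli are
given only in supplementary material not available here, so all are
configurable and these defaults are implementation choices, not the authors'
values.

Non-rigid motion starts from the same rigid backbone and adds:

* **deformation** — each vertex moves along a fixed random unit direction
  (seeded; drawn in the same 3D-level subspace as the irregularity shifts)
  with magnitude `deform_amplitude * sin(2π f_d t)`; default 5 cm, 0.5 Hz;
* **shear** — the shear-axis coordinate is incremented by
  `shear_amplitude * sin(2π f_s t)` times a transverse coordinate; default
  gain 0.2 at 0.5 Hz. The transverse coordinate is the cyclic successor of
  the shear axis (x→y→z→x) — a deterministic, documented choice; the source
  does not specify it.

Both stimuli additionally carry a slight per-vertex jitter "to enhance the
stereoscopy": each vertex oscillates along a fixed random direction with
amplitude 0.5 cm at 2 Hz. The jitter is zero-mean and bounded, so a rigid
stimulus deviates from exact isometry by at most twice the jitter amplitude
in any pairwise distance.

### Projection

4D trajectories are shown as 3D projections. Default is a 4D perspective
projection from a viewpoint at `w = 250` cm: (x, y, z) scale by
`w_eye / (w_eye − w)`, producing the familiar nested inner/outer-cube
tesseract rendering; orthographic (drop w) is a switch. The source does not
state which was used, nor the virtual viewing distance; both are config
parameters (`view_distance` defaults to 150 cm).

3D snapshots project to left/right-eye pixel coordinates by a standard
per-eye pinhole: eyes at ±half the interocular distance along x at
`z = view_distance`, focal length the 18 mm pupil-to-lens distance converted
to pixels through the physical pixel pitch of the 1,200 × 1,080, 91.4 mm
screens. Axes follow the display convention: x rightward, y *downward*,
z out of the screen toward the viewer. Lens distortion and the VR runtime
are out of scope — the headset enters only through these parameters.

## Rigidity oracle

`assess_rigidity()` is the pipeline's ground truth: per frame, the maximum
relative deviation of any pairwise inter-vertex distance from its frame-0
value; rigid iff the maximum over frames is below tolerance. It also reports
a per-frame RMSD after optimal proper-rotation-plus-translation alignment
onto frame 0 (d-dimensional Kabsch; reflections excluded because physical
motion cannot mirror the object). With jitter on, the default tolerance is
`3 × jitter_amplitude / side_length` (0.015 at the defaults), treating
jittered rigid stimuli as rigid by design. Caveat: deviations are relative
to each pair's own frame-0 distance, so a strongly perturbed object whose
vertices come very close together can exceed this default under jitter;
for strict verification disable jitter or pass an explicit tolerance.

Two facts anchor the pipeline and are asserted in the test suite: rigid
native-dimension trajectories conserve all pairwise distances to 1e-9
(jitter off), and a rigid 4D trajectory *fails* 3D rigidity after perspective
projection — the premise of the task, one dimension up.

## Experiment designs

A trial presents two stimuli top/bottom — one rigid, one non-rigid, both at
the trial's irregularity level with the trial's displacement axis — and the
observer reports which was rigid (2AFC), within a 3,000 ms window; overtime
responses are never recorded. Confidence (1 = guessing … 5 = firm belief)
follows each response.

* **Experiment 1** (fixed headset): dimension {3D, 4D} × axis {x, y, z} ×
  irregularity {0.12, 0.18, 0.24}, 3 repetitions → 54 trials per session;
  three sessions per subject, the first flagged `training` and excluded from
  analysis by default.
* **Experiment 2** (active headset): the x axis is removed; 12 cells × 7
  repetitions → 84 trials; two sessions, no training.

With five subjects this yields 5 × 2 × 54 + 5 × 2 × 84 = 1,380 recorded
trials. "Counterbalanced order" is realized as equal per-cell counts with a
seeded permutation within each dimension block (the source defines no finer
scheme); 3D and 4D trials sit in separate blocks whose order alternates
across sessions (unstated in the source; a documented choice). The rigid
stimulus's top/bottom position is balanced within each cell's repetitions,
odd remainders resolved by a seeded coin flip — whether the original design
balanced or fully randomized this is unstated.

## Synthetic observer

The observer is a configured responder, not a cognitive model. Per condition
cell it holds an accuracy probability, RT mean/SD, and confidence mean/SD —
the default bundles `"table1"` (fixed headset) and `"table2"` (active
headset) transcribe the study's printed per-condition tables. Mechanisms:

* **choice** — correct with the cell's accuracy probability;
* **RT** — log-normal (a standard positively skewed RT family; the source
  reports only means and SDs) matched to the cell's mean/SD and truncated to
  (0, 3000] ms by rejection. Because the printed means are themselves means
  of *recorded* (≤ 3 s) responses, the log-normal location is calibrated at
  profile construction so that the truncated mean equals the configured mean
  (closed-form truncated-log-normal mean, one-dimensional root);
* **confidence** — a latent normal coupled to the standardized log-RT draw
  with coefficient ρ ≤ 0 (default −0.6), then rounded and clipped to 1..5.
  The latent location is likewise calibrated so the discretized mean equals
  the configured mean — clipping at 5 would otherwise bias high-confidence
  cells low by more than the n = 2000 recovery tolerance. Discretization
  attenuates the realized confidence–RT correlation below |ρ|; pooling
  across cells (high-RT cells also have low confidence means) strengthens
  it again, and the pipeline's pooled sample correlation lands near the
  −0.5 regime reported for human data;
* **timeouts** — uniform rate 0.045, the study-wide 63/1,380 overtime
  share (per-condition rates are not printed);
* **head pose** — 54 samples at 18 Hz over 3 s. Fixed mode is the constant
  front view. Active mode is, per axis, a stationary AR(1) series (lag-1
  coefficient 0.9, chosen to make drifts slow relative to the 18 Hz
  sampling) around the configured median with marginal SD set from the
  configured interquartile range (IQR = 2·Φ⁻¹(0.75)·σ). Defaults: y median
  45° (the angle the human data concentrated around), x and z medians 10°,
  IQR 2° per axis — small within-trial ranges, as observed.

What the generator emulates is the *per-cell mean/SD structure* of recorded
responses and the gross head-pose statistics. It does not emulate
sequential effects, learning, per-subject heterogeneity (all subjects share
a profile unless given different ones), RT–accuracy interactions within a
cell, or any dependence of responses on the actually rendered stimulus. A
green recovery test therefore establishes that the analysis stage correctly
estimates what the generator put in — not that the perceptual claims hold.

## Analysis

`filter_trials()` drops training sessions, removes all timed-out trials,
and excludes subjects whose overall accuracy is statistically
indistinguishable from chance (two-sided exact binomial test against 0.5 at
α = 0.05) *and* whose mean confidence is below 2.0. The source states the
outcome of its subject exclusion (a subject at 54.9% accuracy with mean
confidence 1.71 was removed) but not the criterion; this conjunction is our
formalization — low confidence corroborates that near-chance accuracy
reflects genuine inability rather than response error. RT analyses use
correct trials only.

`summarize_conditions()` reports per-cell means and SDs; accuracy is
summarized on the per-trial 0/100 indicator, which is how a cell mean of
98.84 can carry an SD of 10.78. Empty cells are NA, never zero.

`lmm_anova()` fits a linear mixed model by REML (lme4) with the requested
fixed factors (all interactions) and a random intercept per subject, under
sum-to-zero contrasts, and reports per-term F tests. Denominator degrees of
freedom use the Satterthwaite approximation, implemented directly on the
REML deviance: variance parameters on the SD scale, their covariance as
twice the inverse numerical Hessian of the (non-profiled) REML deviance, and
per-eigenvector dfs of each term's contrast covariance combined in the
standard way. This is the approximation behind the fractional denominator
dfs customary in this literature (e.g. F(2, 5.15)); it is recorded in the
output metadata (`ddf_method`). If the variance-parameter Hessian is
singular the residual df is used as a documented fallback. Both trial-level
(0/1) and aggregated (per-subject percentage) accuracy analyses are
available via `aggregate =`, since the source does not state which was fit;
trial-level is the default. Note the F-test treats the 0/1 outcome as
Gaussian, as the source's LMM-ANOVA does.

`confidence_rt_correlation()` is the trial-level Pearson test.
`head_movement_stats()` reports per-trial, per-axis medians and percentile
ranges (Q3 − Q1, robust to outliers); quartiles use R's default type-7
interpolation — a documented choice, the source being silent — and the
companion `visual_angles()` computes angles from raw poses as the per-axis
angle between the viewing direction and the head-to-object vector, both
projected onto the plane perpendicular to the axis in question.

Reproducing the study's human F statistics, p-values, and the head-pose ×
performance correlation table is out of scope: they depend on raw human
data that are not deposited. The pipeline's targets are structural counts,
geometric invariants, and parameter recovery of the synthetic observer.

## Numerical and reproducibility choices

* Every stochastic operation takes an explicit integer seed; child seeds are
  derived deterministically and kept within 32-bit range. Same seed, same
  bytes — `run_pipeline()` bundles are byte-identical under a fixed config.
* Rigidity tolerances: 1e-9 relative for exact isometries (accumulated
  floating-point error in composed rotations is ~1e-15); 1e-3 for declaring
  non-rigidity of projected or sheared motion; `3 × jitter / side` when
  jitter is on.
* Kabsch alignment flips the smallest singular direction when the optimal
  orthogonal map has negative determinant, keeping the fit within proper
  rotations.
* Degenerate inputs fail loudly: < 2 frames or vertices, a single subject,
  factors with one level, constant responses (flagged `degenerate`),
  vertices at or behind a projection viewpoint, confidence outside 1..5
  (protocol violation).

## Known limitations

* The motion free parameters are stand-ins for unavailable supplementary
  equations; conclusions about stimulus *appearance* should not lean on the
  defaults.
* The synthetic observer is distributional, not perceptual: it never looks
  at the rendered stimulus (an ideal-observer model over 2D image sequences
  is future work).
* The LMM assumes Gaussian errors even for the 0/1 accuracy outcome,
  mirroring the source's analysis rather than a logistic alternative.
* Active-mode head traces are stationary AR(1) drifts; real exploratory
  strategies (saccadic re-orientation, slow scanning sweeps) are not
  modelled, which is one reason the head-pose × performance correlations of
  the original study are not reproduction targets.
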