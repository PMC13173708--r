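---
title: "Beam-band guided dose prediction and auto-planning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam-band guided dose prediction and auto-planning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`arcdose` is a desk-scale research toolkit for studying an end-to-end VMAT
auto-planning workflow on synthetic pelvic phantoms: directional beam-band
geometric priors, a two-stage cascaded dose-prediction model with a
composite training objective, a DVH-driven iterative inverse-planning loop
against a surrogate optimizer, and a full dose/DVH/gamma evaluation stack.
This vignette records the model, its assumptions, the parameters that
matter, and the design decisions that were genuinely open.

## The synthetic study system

Clinical cohorts and commercial planning systems are out of reach for a
reproducible desk-scale package, so every experiment here runs on phantoms
from `generate_phantom()`. A phantom emulates a female pelvis: an
elliptical body per axial slice, an ellipsoidal central target (PTV),
bladder anterior and rectum posterior to it, a posterior midline
spinal-cord column, lateral femoral heads, a bony shell standing in for
pelvic marrow, and three superior/anterior small-intestine blobs. CT
values are −1000 HU outside the body, ~0 HU soft tissue and ~700 HU bone,
with additive Gaussian noise (σ = 20 HU) so the CT channel is
non-degenerate without modelling acquisition physics. Organ centres and
semi-axes receive uniform jitter (±6 mm, ±8% by default); with both jitter
ranges at zero the geometry is seed-independent, which the tests exploit.

The default grid is 64×64×32 voxels at (2.5, 2.5, 5) mm — 5-mm slices at a
CPU-friendly in-plane resolution. The test-suite and the acceptance script
run one size down, 32×32×16 at (5, 5, 10) mm over the same 160 mm physical
extent, with base network width 8; these sizes are the package's study
configuration and are stated wherever results are produced. The
prescription is 45 Gy (25 fractions), and all dose normalisation uses it.

Reference doses come from a deliberately simple parallel-ray engine:
`forward_dose()` deposits `exp(-mu * depth)` along parallel rays at each
gantry angle (default eight angles over a full arc, mu = 0.004/mm), inside
the body only, linearly in the beam weights. The engine's only job is to
give reference plans the directional corridor structure that arc
deliveries exhibit; it makes no claim to dosimetric realism (no
divergence, scatter, or heterogeneity corrections). Reference plans are
produced by `generate_reference_plan()`, which runs the package's own
inverse optimizer under clinical-style objectives and rescales the result
so the PTV mean equals the prescription. What passing tests show is
therefore that the *workflow* behaves correctly on data with the right
structure — not that any component is validated against clinical dose.

## Beam-band priors

On each axial slice, the band at angle θ is the corridor between the two
lines parallel to the beam direction and tangent to the PTV
(`band_mask_slice()`). Discrete tangency uses pixel-centre inclusion with
a closed interval: a pixel belongs to the band when the projection of its
centre onto the beam normal lies within the range of the PTV pixel-centre
projections. This avoids partial-pixel logic and is exactly reproducible;
the price is a ±1-pixel ambiguity at the boundary, which the
rotation-invariance test (band width of a disk within 2 px across angles)
bounds. Angles live in [0, 180) because a band at θ equals the band at
θ + 180; `make_band_set(k)` uses angles i·180/k, so k = 4 gives the
canonical 0/45/90/135 set. Bands are built per slice and stacked — no 3D
tilting — and are not clipped to the body by default (a `clip_body`
argument exists).

For the band-count ablation, the coverage statistic is the fraction of
thresholded dose mass (default: voxels at or above 50% of the maximum)
that falls inside the band union. The exact clinical statistic this
mirrors is not fully specified anywhere we could rely on, so the
thresholded-dose-mass definition is the documented surrogate, exposed as a
configurable threshold. Monotonicity in k is only guaranteed for nested
angle sets, so `ablate_bands()` adds angles in a fixed bisection order
(0, 90, 45, 135, 22.5, …) and smaller arms are always subsets of larger
ones.

## The two-stage cascade

Stage 1 is a plain 3D U-Net (depth 3, two 2×2×2 average-pooling levels,
3×3×3 convolutions, skip connections by channel concatenation) mapping 10
channels — CT clipped to [−1000, 1000] HU and scaled to [0, 1], plus the
nine binary structure masks — to a normalized dose through a softplus
output, trained with body-restricted MAE. Stage 2 is the same topology
with residual blocks (1×1 projection shortcuts where channel counts
change) over 15 channels — the 10 Stage-1 channels plus the
prescription-normalized coarse dose and the four band masks — and predicts
a *correction*: the refined dose is `max(coarse + delta, 0)` with a
zero-initialised head, so refinement starts exactly at the coarse dose.
Whether the refinement stage should predict dose directly or a residual
was an open choice; the residual form matches the refinement semantics and
stabilises small-cohort training, so it is the default.

No deep-learning framework is used: convolutions run as chunked
im2col + BLAS GEMM in compiled code, the backward pass is hand-chained,
and the optimizer is Adam (lr 1e-3, batch size 1). Every gradient path is
validated against central finite differences in the test-suite (1e-4
relative for the losses, 1e-5 for the networks). Training is deterministic
given the seed, which fixes initialisation and per-epoch case order; the
best-validation checkpoint is retained. Stage 1 stays frozen while Stage 2
trains — the cascade is trained sequentially, not jointly.

## The composite refinement objective

Stage 2 minimises a weighted sum on prescription-normalized dose:

L_total = λ_body·L_body + λ_band·L_band + λ_grad·L_grad + λ_DVH·L_DVH

* **L_body** — MAE over body voxels (global accuracy).
* **L_band** — MAE restricted to the band union (band-region fidelity).
  Averaging over the union rather than per-band-then-over-bands was an
  open choice; the union form is simpler and insensitive to band overlap.
* **L_grad** — mean L1 distance between spacing-aware central-difference
  gradient *vectors* of the two doses over the band union (comparing
  vectors, not magnitudes, penalises direction errors too).
* **L_DVH** — a differentiable DVH surrogate: per ROI, the soft cumulative
  curve `s(b) = mean(sigmoid((d - b)/T))` on a fixed bin grid
  (default 25 bins over [0, 1.2] normalized dose), with the loss the mean
  absolute difference between the predicted and reference curves. The
  temperature T defaults to 0.02 normalized dose ≈ 1 Gy at 45 Gy: soft
  enough for useful gradients, sharp enough that the T → 0 limit recovers
  the hard DVH distance (verified on a two-voxel toy in the tests).

The weights default to (1, 1, 1, 1): no principled values are available,
and equal weighting on normalized dose is the neutral choice; all four are
configuration. Components with zero weight are skipped entirely, so
ablation arms pay no cost for absent terms.

## The planning loop

`extract_targets()` evaluates the protocol metrics on the refined
prediction to form the goal table M0. `assemble_objectives()` maps each
row to one objective — target metrics to lower bounds (or uniformity
caps), OAR metrics to upper bounds — with weights from the protocol.
`optimize_beamlets()` minimises weighted one-sided quadratic penalties
over non-negative beamlet weights (eight arc angles × 16 lateral strips by
default) by projected gradient descent with an adaptive, monotone
backtracking step; it is fully deterministic. Volume-type constraints
(V_d ≤ v%) penalise only the violating voxels closest to the threshold,
the cheapest set whose removal restores the constraint.

`iterate_plan()` then closes the loop: optimize, compare the achieved
metrics Mc against M0, and for every unmet metric tighten *only that
objective's* working goal by 2% (lower bounds × 1.02, upper bounds
× 0.98), re-optimize, stopping early when everything is met and never
exceeding five iterations; the retained iteration minimises the aggregate
scale-normalised violation, ties going to the earliest. Three choices
here were genuinely open and are resolved as follows: the 2% step is
applied to the constraint *dose/volume value* (not the weight); all unmet
objectives update simultaneously (a five-iteration cap precludes
one-at-a-time updates); and iteration 1 uses M0 exactly, without protocol
margins. A metric counts as met within a scale-normalised tolerance of
0.002 (0.09 Gy at 45 Gy, or 0.2 percentage points), which absorbs
optimizer granularity without masking real violations.

## Evaluation stack

DVH endpoints follow the standard grammar (Dmax, Dmean, D{p}%, V{d},
V{p}%, HI, CI). D{p}% interpolates linearly between order statistics;
Dmax is the single hottest voxel (no volume qualifier at a 3–10 mm grid);
HI = (D2% − D98%)/D50%; CI is the Paddick index at the prescription
isodose, with the RTOG ratio available by option. DVH curves use 0.1 Gy
bins; endpoints are computed from the voxel samples directly, not from
the binned curve. The dose score is the body-restricted MAE in Gy; the
DVH score the mean absolute endpoint difference over a spec (default:
target D2%/D98%/Dmean, every OAR Dmean/Dmax); the scale-normalised DVH
score divides each endpoint difference by the prescription (D-type), 100
points (V-type) or 1 (HI/CI) and sums over the spec, making mixed
endpoint sets commensurate in one dimensionless number per case. The exact normalisation of the clinical scale-normalised
score is not public, so this definition is the package's documented
surrogate; its absolute values are not comparable to clinical reports.

Gamma analysis is global: the dose-difference criterion is a percentage
of the *reference* maximum, voxels below 10% of that maximum are
excluded, and gamma is minimised over displacements on a 3× refined grid
(spacing/3 steps) within a radius of 3 × DTA, with trilinear
interpolation of the evaluated dose. Candidates are visited in order of
increasing distance so the distance term alone terminates the search.
Because normalisation and voxel selection come from the reference, the
statistic is not symmetric under swapping the two doses; the reference is
always the first argument. The implementation is cross-checked in the
tests against an exhaustive, independently coded search.

## Study sizes, budgets and limitations

The training-based checks use a 10-case cohort (8:1:1 split) on the
32×32×16 grid, width 8, 20 Stage-1 epochs, 8 Stage-2 epochs and three
seeds — sizes chosen so the whole suite runs on one CPU core in well
under half an hour while leaving the learning signal clearly measurable
(Stage 1 beats the zero-dose predictor by far more than the 30% margin
the tests require, and the refined dose improves on the coarse one in
median). The loss-term ablation compares the four cumulative arms (body;
+band; +gradient; +DVH) under identical seeds and splits and asks for a
directional result — median test dose score non-increasing.

One honest negative deserves recording: on this synthetic cohort the
pure body-MAE arm consistently attains the *best* dose score, by about
1% and systematically across seeds, so the non-increasing ordering along
the cumulative arms does not hold here. The mechanism is plain: the dose
score *is* the body MAE, the baseline arm trains exactly that
functional, and with eight training cases the band/gradient/DVH terms
reallocate capacity toward corridor and endpoint fidelity without the
real-data structure (planner variability, anatomy–dose misalignment,
cohort-scale regularisation benefits) that makes those priors pay off
clinically. The corresponding check is left in place and failing rather
than weakened; the DVH-oriented terms do what they claim locally (their
unit-level closed forms and gradients all verify), but their cohort-level
benefit is not reproducible at this scale.

Known limitations: the dose engine is parallel-ray and homogeneous; the
phantom's organ shapes are analytic and its CT texture is noise, not
anatomy; the surrogate optimizer has no aperture or delivery constraints,
so "deliverability" here means agreement between the planned and
reference dose fields, not machine QA; and all scores on synthetic data
sit on different absolute scales than clinical cohorts. Conclusions that
transfer are structural — tangency and coverage properties of the bands,
correctness of the losses and their gradients, the contract of the
planning loop, and the direction of the cascade's improvements.
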