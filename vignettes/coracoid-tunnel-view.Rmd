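---
title: "Planning coracoid screw corridors under virtual fluoroscopy"
author: "ctvsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning coracoid screw corridors under virtual fluoroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctvsim)
```

## The problem

Fixation of a coracoid base fracture asks the surgeon to drill a screw down a
narrow, obliquely oriented bone tunnel — the coracoid stalk, through its base,
into the scapular neck — guided only by fluoroscopy. The decisive insight of
the *coracoid tunnel view* (CTV) is geometric: if the C-arm is oriented so
that the central X-ray beam is collinear with the tunnel axis, the tunnel
projects as an oval and a correctly oriented screw projects as a **dot**.
Finding that view, placing a screw perpendicular to it, and judging the
placement against three criteria (tunnel traversal, parallelism to the
glenoid fossa, no cortical breach) is an entirely geometric pipeline, and
`ctvsim` implements it end to end on synthetic CT-like volumes.

The package has six cooperating parts: a voxel-volume data model with
MetaImage/NIfTI I/O and an exact anisotropic Euclidean distance transform; a
parallel-beam DRR renderer (the virtual fluoroscope); crosshair-driven screw
placement; the inscribed-cylinder corridor search that defines the CTV; the
three-criterion scorer; and the statistics of a paired two-session rater
study (exact McNemar, ICC(A,k), exact power).

## Phantoms and what they stand in for

No cadaver CT data are distributed, so every pipeline stage runs on phantoms
with analytically known ground truth:

* **capsule** — a cylinder with hemispherical caps: the idealized tunnel.
  Ground truth: exact axis, constant clearance.
* **sphere** — used for the renderer's chord-length contracts and for the
  corridor search's closed-form optimum (a corridor of length $L$ inside a
  sphere of radius $R$ has bottleneck clearance $R - L/2$).
* **scapula analog** — an oblique corridor capsule labelled stalk/base/neck
  in thirds, a thin blade plate attached beyond the neck end, and a glenoid
  disc whose plane *contains* the corridor axis, so the ground-truth screw is
  parallel to the glenoid by construction. A seed perturbs radius (±5%),
  obliquity (±3°) and blade thickness (±10%), standing in for anatomical
  variation across specimens.

Default geometry: corridor radius 4 mm, length 35 mm, 1 mm isotropic voxels
(0.45 mm, matching a high-resolution CT protocol, is available but desk-scale
tests use 1 mm), bone 700 / background −1000 on an HU-like scale with
segmentation threshold 150. What the phantoms deliberately omit: cortical
density gradients, trabecular texture, soft tissue, over-projection of
surrounding bodies, and real anatomical variation. Passing tests therefore
demonstrate the *geometric* correctness of rendering, search and scoring —
not segmentation robustness on clinical CT.

The sphere phantom is edge-antialiased (intensity ramps linearly across one
voxel at the surface) so that line integrals through it reproduce analytic
chord lengths within 1% at 1 mm spacing; masks for corridor and breach work
stay hard-thresholded because those stages need crisp inside/outside
geometry.

## Rendering model

The virtual fluoroscope is a parallel-beam DRR: each detector pixel holds
$\int \mu(x)\,ds$ along its ray, sampled midpoint-wise at half the smallest
voxel pitch with trilinear interpolation, with
$\mu = \mu_\text{water}\max(I + 1000, 0)/1000$ and
$\mu_\text{water} = 0.02\,\text{mm}^{-1}$. Parallel beams (not cone-beam)
make the screw-as-a-dot condition exact rather than approximate, which is
the property the protocol rests on. Orientation lives entirely in the view
state — a unit quaternion plus detector centre and crosshair — volumes stay
axis-aligned. Display windowing is the usual clamped affine map; the study
chose brightness/contrast qualitatively, so window and level are free
parameters here.

```{r render}
ph <- make_scapula_analog(seed = 1)
img <- render_drr(ph$volume, view_state(), projection_geometry(96, 96, 1, 0.5))
img
```

## The corridor search and its numerics

The optimal corridor maximizes the *bottleneck clearance*

$$ f(p, d) = \min_{t \in [0, L]} D\!\left(p + t\,d\right), $$

where $D$ is the Euclidean distance-to-cortex map. The minimum (not the
mean) is the right aggregate because a single cortical encroachment must
dominate — this is exactly the "screw must not bulge outside the tunnel"
notion, and $f$ at the optimum is the largest screw radius that fits.

The search is deterministic, with no random restarts:

1. **Coarse stage** — evaluate $f$ on a 200-direction Fibonacci sphere
   crossed with a 3×3×3 grid of start offsets (±ball/√3 per axis, ball
   radius 10 mm around the seed).
2. **Length continuation** — a long, narrow tunnel subtends only a few
   degrees of direction space, far less than the coarse grid resolution, so
   the search first solves a short corridor (12 mm, wide basin), then
   extends through ⅔-length to full length, re-seeding each stage from the
   survivors.
3. **Simplex refinement** — Nelder-Mead on five parameters (three point
   offsets, two tangent-plane direction angles), run at two parameter scales
   (2 mm / 0.1 rad, then 0.5 mm / 0.02 rad) with restarts; the kinked
   min-objective stalls a single plain simplex run.
4. **Diversity** — at each stage several mutually distinct candidates (by
   direction and position) are carried forward, so a broad shallow basin
   (e.g. inside the blade plate) cannot crowd out the tunnel basin.

Two numerical details matter. First, the axis of an inscribed cylinder is
sign-symmetric, so the ball constraint is applied to whichever segment end
lies nearer the seed, and candidates are canonicalized to start at that end
(the returned axis direction is then disambiguated against an orientation
hint, world $+z$ by default). Second, the distance map measures to the
nearest *background voxel centre*, which biases clearances low by roughly
half a voxel; recovered bottleneck radii on a 5 mm capsule land near
4.5 mm at 1 mm spacing, within the one-voxel agreement the package promises.

```{r corridor}
mask <- segment_bone(ph$volume)
dmap <- distance_map(mask)
cor <- find_corridor(dmap, ph$truth$axis_point + 15 * ph$truth$axis_dir, 30,
                     orient_hint = ph$truth$axis_dir)
summary(cor)
```

The CTV is then simply the view whose central ray is the corridor axis, with
the crosshair at the detector origin, so the crosshair ray *is* the corridor
axis:

```{r ctv}
ctv <- ctv_from_corridor(cor)
ctv
```

## Placement and scoring

`crosshair_to_cylinder()` reproduces the placement interaction: the screw
axis is the viewing direction (perpendicular to the detector plane), the
entry point is the first crosshair-ray/bone intersection refined to <0.01 mm
by bisection, and `"auto"` length seats the screw at the last cortex exit
within 100 mm. A tangential graze is rejected as a non-drillable entry.
The default radius, 1.75 mm, is a 3.5 mm cortical screw; the original
software's screw diameter is not reported, so it is a parameter.

Scoring applies the three criteria:

* **Traversal** — the axis must visit stalk (1), base (2), neck (3) labels
  as an ordered subsequence; direction matters, so a reversed screw fails.
* **Parallelism** — the angle between the screw axis and the glenoid plane,
  $|90° - \arccos(d \cdot n)|$, must not exceed a tolerance. The study
  states the criterion without a number; the default is 10° and every result
  records the tolerance used.
* **Breach** — at 1 mm stations along the axis, trilinear clearance must
  satisfy $\text{clearance} + \varepsilon \ge r$ with
  $\varepsilon = \tfrac12\sqrt{s_x^2+s_y^2+s_z^2}$ (half the voxel
  diagonal): an exact-touch screw on a discretized map is not a breach.

One scoring decision was genuinely open. A screw placed from the surface
*starts on* the cortex — its entry clearance is near zero by construction —
and it seats *into* the far cortex; neither transit violates the tunnel's
side walls, which is what the breach criterion is about. `score_placement()`
therefore excludes one screw radius of axis at each end from the breach
check (`entry_exit_trim = 0` restores the literal whole-axis test, which
`breach_test()` itself always implements). Screw length and depth otherwise
play no role in the rating, mirroring the study's rule; scoring the same
trajectory at 25/30/35 mm yields identical ratings.

```{r score}
cyl <- crosshair_to_cylinder(mask, ctv, radius = 1.75, length = "auto")
score_placement(cyl, ph$truth, dmap)
```

## Study statistics

The rater-study layer reproduces the design: 8 surgeons × 14 scapulae × one
screw each, sessions on disjoint halves (7 + 7), 112 placements. Percentages
are rounded half-up to one decimal the way the study prints them
(33/56 → 58.9, 50/56 → 89.3, improvement 30.4 points). The McNemar test is
the exact conditional binomial on the discordant pairs by default (the
asymptotic χ² with continuity correction is available); pairs are formed by
(rater, scapula-rank within session), a choice the study leaves unstated and
which is recorded in the output. ICC(A,k) — two-way, absolute agreement,
average measures — is computed from the two-way mean squares with the
McGraw–Wong confidence construction and the standard reliability bands
(<0.5 poor, 0.5–0.75 moderate, 0.75–0.9 good, ≥0.9 excellent). Power for the
paired design is exact: the trinomial distribution of the discordant cells is
enumerated and the rejection probability summed — a principled substitute for
the study's unstated power method, not a replication of its 0.94.

Degenerate corners are handled explicitly: no discordant pairs gives p = 1;
a perfectly agreeing rating matrix gives ICC = 1 with a point CI; when
residual variance exceeds subject variance the ratio estimator can leave
[0, 1], and such worse-than-chance agreement is reported raw but banded as
poor; a confidence bound whose Spearman–Brown step-up crosses its pole is
reported as non-estimable (−∞) rather than silently wrapped.

```{r stats}
study <- simulate_study(seed = 42)  # defaults: the observed session rates
report <- study_report(study)
str(report[c("before", "after", "improvement_pp", "mcnemar")])
```

## Problem sizes and limitations

The test-suite and acceptance runs use 1 mm phantoms (volumes of roughly
50–90 voxels per side), 200-direction coarse grids, and 10-capsule /
single-analog corridor batches; a corridor search takes a few seconds at
this scale, and the whole verification pipeline a few minutes. Finer spacing
sharpens every quantization-limited figure (clearance bias, silhouette
areas) at cubic cost in voxels.

Known limitations: parallel-beam only (no cone-beam divergence, scatter or
detector noise); no anatomical-landmark detection — the human protocol of
aligning landmarks until the oval tunnel appears is represented only by its
geometric endpoint, the axis-aligned view; threshold segmentation stands in
for the study's unspecified segmentation pipeline; and the scorer is a
deterministic rater, so human inter-rater disagreement enters only through
the stochastic study simulator, never the geometry.
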