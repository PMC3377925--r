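---
title: "Geometry-driven single-segment IMRT planning: models and methods"
author: "TwoStepIMRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-driven single-segment IMRT planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The planning problem

Step-and-shoot IMRT delivers a plan as a sequence of static multi-leaf
collimator (MLC) apertures ("segments"), each from a fixed gantry angle with
a fixed weight in monitor units. Conventional inverse planning produces
several segments per beam; every extra segment costs shaping time, and on
older accelerators every extra *beam* costs a per-beam data-handling delay.
The alternative implemented here distributes *single-segment* beams over
many gantry angles so that leaf motion happens concurrently with gantry
rotation, and derives each aperture directly from the topology of the
planning target volume (PTV) and the dominant organ at risk (OAR) instead of
from fluence-map optimization followed by leaf sequencing.

Three aperture orders are constructed from the beam's-eye-view (BEV)
projections of PTV and OAR:

* **S0** (conformal): per leaf pair, the full travel-axis extent of the PTV
  shadow — the row-wise convex hull. It smooths the target dose but does not
  spare the OAR.
* **S1** (blocking): covers the PTV while blocking the margin-expanded OAR
  shadow, opening only the chosen side of the OAR so consecutive beams need
  little leaf travel. It spares the OAR but underdoses the PTV rim next to
  it.
* **S2** (rim strip): a narrow strip immediately beside the expanded OAR
  shadow, limited to the S0 row interval and to rows where the OAR is
  present. It saturates the rim that S1 leaves cold — a discretized form of
  the sharp fluence peak that concave-target theory calls for at the OAR
  boundary.

A *Fast* plan assigns one order per angle by cyclic repetition of a pattern
(for example `{S1 S2}` over 30 angles, or `{S0 S1 S2}` when conformal
segments are acceptable), so the number of segments equals the number of
retained beams. If neither a valid S1 nor S2 aperture exists at an angle,
the beam is discarded. A conventional multi-segment reference plan is built
by taking every valid order (optionally both sides of the OAR for S1/S2) at
each of a smaller number of angles.

## Beam and aperture geometry

Beams are coplanar, with leaf pairs stacked along the patient longitudinal
axis and leaf travel in the axial plane; the gantry angle follows IEC 61217
(0° anterior, clockwise viewed from the feet). The published study does not
state its angle convention or start angle; results here are rotation
invariant by construction and the start angle is a parameter. Projections
are divergent (point source, source-axis distance 1000 mm by default)
onto the isocenter plane: each structure voxel is projected through the
source and splatted onto a raster whose columns sample the travel axis
(default 2 mm in the planning functions, at most half a leaf width) and
whose rows are MLC leaf pairs on an absolute leaf-width lattice, so masks of
different structures align cell-by-cell. Apertures hold at most one open
interval per leaf pair — the step-and-shoot deliverability contract.

Open geometric parameters were fixed once as follows and are exposed as
`segmentationParams()`:

* **OAR block margin** (default 3 mm): expansion of the OAR shadow before
  blocking, approximating the beam penumbra.
* **S2 strip width**: the geometric derivation in the original two-step
  literature is not reproduced here; the default rule takes a quarter of the
  chosen-side PTV extent beyond the OAR edge in the central OAR row, clamped
  to [5, 30] mm — "generally narrow", scaled to the unsaturated region.
* **Aperture validity threshold** (default 1 cm² open area): an aperture
  below the threshold is invalid and its beam discarded. The threshold sits
  deliberately below the area of a typical rim strip on the bundled
  phantoms (roughly 1.4–1.8 cm²): rim segments are narrow by design, and a
  larger threshold would discard every S2 beam and collapse the alternating
  pattern, while 1 cm² still rejects degenerate slivers.
* **Side** (default left, the smaller BEV travel coordinate): the common
  side of the dominant OAR opened by S1/S2 at every angle, minimizing
  inter-beam leaf travel.
* Rows where the OAR shadow fully covers the PTV row are closed in S1 and
  S2: blocking has priority over coverage.

## Dose engine

The engine is a calibrated primary-fluence model, deliberately simple: the
claims under test (segment geometry, timing arithmetic, comparative
objective scores) need a physically monotone, linear engine rather than
clinical-grade dose. Per unit weight,

$$ d(\mathbf{x}) \;=\; \mathrm{OF} \cdot
   \Phi\!\left(x_\mathrm{bev}\right) \cdot
   e^{-\mu\, (z_\mathrm{rad}(\mathbf{x}) - 100\,\mathrm{mm})} \cdot
   \left(\frac{\mathrm{SAD}}{r(\mathbf{x})}\right)^{2}, $$

with $\Phi$ the aperture fluence along the travel axis (error-function edge
profile, Gaussian penumbra $\sigma$ = 3 mm by default), $\mu$ = 0.005/mm
(approximately 6 MV in water), $z_\mathrm{rad}$ the radiological depth in
the unit-density body, and $r$ the source distance. The output factor OF is
set by `calibrate()` so that 100 effective monitor units (MU_eff) deposit
exactly 1 Gy on the central axis of a 100 × 100 mm field at 100 mm depth —
the MU_eff normalization all weights use. There are no scatter kernels, no
heterogeneity, no MLC transmission; leaf ends are penumbra-free along the
stacking axis.

Radiological depth is computed by counting upstream body voxels in
one-voxel-wide ray bins (exact for axial beams on isotropic grids, an
adequate approximation at oblique angles). The influence matrix stores dose
per *beamlet* (leaf row × travel step): because error-function edge profiles
of adjacent beamlets telescope, the sum of a segment's beamlet columns
reproduces the full-aperture profile exactly, and aperture fine-tuning
re-scores by adding or removing single columns. Beamlet kernels are
truncated 4σ beyond their edges (relative tail loss below one percent,
verified against the direct trace in the test-suite).

## Objectives, COV and S_D

Objectives are weighted one-sided quadratic penalties on DVH points
$D_v$ (the largest dose received by at least $v$% of a structure's volume):
a lower bound contributes $w\,\max(0, C - D_v)^2$, an upper bound
$w\,\max(0, D_v - C)^2$, with $C$ and $D_v$ in percent of the reference
prescription. Templates per bundled case follow the standard pattern — two
terms near the minimum dose ($D_{100} > 95$, $D_{98} > 97$), two near the
maximum ($D_{02} < 102$, $D_{00} < 104$), a central-plateau window per
target (scored on an eroded copy of the target, erosion radius 4–5 mm), up
to three DVH-shaping terms per OAR — with per-case counts 14 (horseshoe),
21 (nested-boost prostate-like), 28 (nested-boost spine-like) and 25
(tangent), and all weights in [0.1, 100]. The numeric dose levels and
weights of the original per-case objective sets are not published; the
templates reproduce the documented pattern and counts with configurable
values.

The **composite objective value (COV)** is the sum of all weighted
penalties; lower is better, and plans are compared by COV normalized to a
reference plan (differences beyond +25 %/−20 % count as relevant). The
**dose-shortfall score** $S_D$ sums $|M_j - C_j|$ over *violated* objectives
only, in percent of prescription ($M_j$ the achieved value); satisfied or
over-achieved objectives contribute nothing, so a plan fulfilling every
objective scores exactly 0 and $S_D$ is independent of the penalty weights.
The percent-of-prescription unit convention for $S_D$ is adopted here
because the objective levels themselves are quoted in percent.

## Optimizer

Shapes and weights of the pre-defined segments are fine-tuned against the
objective set; nothing else is varied. Two consecutive runs of 40 weight
steps each are used (80 iterations in total), and at each run boundary any
segment below 2 MU_eff is discarded.

The weight problem — minimize COV over non-negative segment weights — is
non-smooth in the DVH statistics. Directly stepping on DVH-point
subgradients stalls far from competitive minima, so the optimizer's internal
scoring defaults to a *DVH-aware band surrogate*: each objective is scored
as a per-voxel quadratic over the voxels lying between the current $D_v$ and
the objective level (the standard dose-volume penalty construction). The
surrogate is smooth almost everywhere, and its zero set coincides with the
satisfied objective, so minimizing it minimizes the reported COV's
violations. Search directions are damped Gauss–Newton steps on the surrogate
(with a diagonal-preconditioned gradient and the DVH subgradient as
fallbacks); a backtracking line search accepts only steps that decrease the
configured scoring, so the optimization trace is monotone non-increasing.
Scoring on the raw DVH statistic remains available
(`optimizerConfig(scoring = "dvh")`); *reported* plan quality always uses
the DVH-statistic COV.

Aperture fine-tuning is greedy coordinate descent over leaf positions in
beamlet steps (at most `move_limit` per edge per sweep), accepting only
score-decreasing moves, in a fixed deterministic order (segments in plan
order, rows caudal to cranial, left bank before right). Sweeps are
interleaved with the weight blocks, and a few *pre-conditioning sweeps* run
before the first weight block: shapes adapt while the weight distribution is
still uniform, before weights sharpen into a configuration that individual
leaf moves cannot escape. The default path is fully deterministic; the seed
only exists to freeze any future stochastic component.

## Delivery-time model

The plan delivery time combines gantry transitions, segment shaping,
beam-on time and per-beam data handling:

$$ T \;=\; (n-1)\,\max\{\tau_{GSS},\, \bar\tau_S\}
   \;+\; (N-n+1)\,\bar\tau_S \;+\; MU/\dot D \;+\; (n-1)\,\tau_F, $$

where $n$ is the number of beams, $N$ the number of segments,
$\tau_{GSS} = \tau_{SS} + \Delta\theta \cdot t_{360}/360$ the transition
time for an angular spacing $\Delta\theta$ (start-stop time plus scaled
rotation time; the max term encodes that segment shaping runs concurrently
with gantry motion), $\bar\tau_S$ the mean shaping time, and $\tau_F$ the
data-handling time per beam. Machine presets: **new** linac — 60 s/360°,
$\tau_{SS}$ = 3 s, $\bar\tau_S$ = 7 s, $\tau_F$ = 3 s; **old** linac —
78 s/360°, 3 s, 12 s, 9 s. The published parameter set does not include
dose rates; the defaults of 500 (new) and 350 (old) MU_eff/min were
back-solved once from published plan timings, are flagged as model defaults,
and can be overridden (`machinePreset("new", doseRate = ...)`). Full-circle
plans use $\Delta\theta = 360/n$; partial arcs take the mean gap of the
retained angles. Reports round to 0.1 min; raw minutes are retained.

## Synthetic phantoms

`makePhantom()` builds three voxel phantoms on a water-equivalent elliptic
body (300 × 200 mm by default), as stand-ins for the study's cases:

* **quasimodo** — a horseshoe PTV (inner radius = OAR radius + gap, default
  25 + 5 mm, 20 mm thick, 100° posterior opening) around a central
  cylindrical OAR: a concave target with a dominant OAR, a narrow gap and
  hence stringent gradient demands.
* **sib** — nested target volumes (outer PTV with an integrated central
  boost at a higher prescription) indented by an adjacent OAR, plus a
  secondary OAR: a simultaneous-integrated-boost constellation.
* **tangent** — a crescent PTV wrapped around a large lateral lung-like OAR
  for partial-arc geometry.

Prescriptions are per-fraction doses (2 Gy for the horseshoe and tangent
cases, 1.8/2.3 Gy for the nested-boost case), so segment weights and plan
MU_eff totals come out on the scale of a single treatment session — the
scale on which published per-fraction plan timings are quoted. Because the
engine is linear and objectives are in percent of prescription, every
quality result is invariant to this choice.

Masks are voxel-center rasterizations of analytic shapes without
partial-volume weighting, so they can be tested against analytic oracles;
derived help structures (envelope rings, eroded plateaus, healthy tissue)
are included for the objective templates. The exact dimensions of the
original physical phantom and the original patient anatomies are not
published in a reproducible form; these phantoms are therefore documented
approximations, not reproductions. Grids default to 256 × 256 × 16 voxels at
2 mm; the phantoms are deliberately short longitudinally (a quasi-2.5D
setting) because the horseshoe problem is essentially axial. What passing
tests on these phantoms show is that the segmentation rules, the optimizer
and the scoring behave as specified under controlled geometry; they do not
show clinical dose accuracy on real anatomy, which would require a
clinical-grade dose engine and real contours.

## Numerical choices and problem sizes

* BEV raster and beamlet step 2 mm along the travel axis; one row per leaf
  pair (4 mm leaves in the fine preset).
* Aperture edges snap to the beamlet lattice only through membership
  (beamlet centers inside the interval); fine-tuning moves edges in whole
  beamlet steps.
* Scoring voxels can be thinned deterministically (every k-th voxel) to a
  cap per structure; dose at retained voxels stays exact and DVH statistics
  are computed on the thinned sample.
* The comparative experiment exercised by the test-suite runs the horseshoe
  case on a 128 × 128 × 8 grid. The default 2 mm voxels would give a 256 mm
  lateral extent that cannot hold the 300 mm body ellipse, so 2.5 mm voxels
  are used at that grid shape, with scoring capped at 6000 voxels per
  structure (about 23 000 in total). The single-segment 30-beam plan is
  compared there against a 9-beam reference carrying every valid order with
  both-sided S1/S2 (up to 45 segments), both fine-tuned by the identical
  engine, objectives and schedule.
* Degenerate inputs: empty structures project to empty BEV masks (not
  errors); empty PTV shadows, vanishing strip widths and sub-threshold areas
  yield *invalid* apertures that drive beam discard; an all-discarded plan
  raises an error, as does a grid too coarse to resolve the PTV–OAR gap
  (less than two voxels).

## Known limitations

* The dose engine is a primary-fluence model: no scatter, no build-up, no
  leaf-end effects along the stacking axis. Absolute dose agreement with a
  commercial system is out of scope; only internally consistent comparisons
  are meaningful.
* The optimizer is a compact analog of a commercial direct-aperture engine,
  not an emulation of its numerics; normalized-COV comparisons are
  internally consistent but not comparable to published absolute COV
  values.
* Old-linac delivery-time rows in the published table are not mutually
  consistent under any single dose rate, so the old preset is used for
  structural and sensitivity statements only.
* Aperture fine-tuning never opens a fully closed leaf pair, and the leaf
  travel range is bounded by the influence beamlet extent
  (`padMM` in `buildInfluence()`).
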