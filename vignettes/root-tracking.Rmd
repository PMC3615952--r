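---
title: "Tracking root systems through micro-CT stacks: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking root systems through micro-CT stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rhizotrack)
```

## The problem and the model

X-ray attenuation in a soil column does not separate root from non-root:
organic matter attenuates like root tissue, and root attenuation itself
drifts with depth (water retention, tissue maturation). Any workable
segmentation must (i) target root material explicitly and (ii) adapt to
local change. `rhizotrack` does both by *tracking*: the volume is a stack
of images, a root cross-section is an object that "moves" from slice to
slice, and each tracked object carries its own, continually re-estimated
appearance model.

### Per-slice segmentation

A slice is segmented locally with a discrete narrow-band level set. The
region interior is an explicit pixel set; per iteration, outer boundary
pixels with positive speed join and inner boundary pixels with negative
speed leave, so the contour moves at most one pixel per iteration. The
speed at pixel $x$ with grey value $I(x)$ is

$$F(x) = \alpha\,\bigl(2\,p_{\mathrm{root}}(I(x)) - 1\bigr)
         - (1-\alpha)\,\kappa(x),$$

with $p_{\mathrm{root}}(g) = \tilde h_{\mathrm{root}}(g) /
(\tilde h_{\mathrm{root}}(g) + \tilde h_{\mathrm{bg}}(g))$. Here
$\tilde h_{\mathrm{root}}$ is the object's histogram and
$\tilde h_{\mathrm{bg}}$ a background histogram from a 5-pixel annulus
around the initial region (other tracked objects' pixels excluded); both
are kernel-smoothed over bins before the ratio is formed (below).
$\kappa$ is a discrete curvature, $1 - 2m$ for $m$ the mean 3×3 occupancy:
zero on a straight edge, positive on convex bumps, so the second term is
a smoothness prior and $\alpha = 0$ degenerates to curvature flow (the
region provably shrinks — a unit test asserts this).

Evolution stops at a fixed point, on a period-2 cycle (the discrete update
can oscillate by one boundary pixel; accepting the cycle state keeps the
procedure deterministic), or after `max_iter` iterations. There is no
randomness anywhere in segmentation or tracking.

### Tracking, look-back, and alternating passes

Tracking assumes a root appears at a similar position, size, shape and
attenuation on the next slice: the level set on slice $n+1$ is initialised
with the slice-$n$ footprint and model. Connected components of the result
let the target split at branch points; each component at least `min_area`
pixels becomes a child that inherits the parent model and replaces it with
its own observed histogram only if the Bhattacharyya coefficient reaches
$\beta$ (inclusive). When two parents' evolutions claim the same
component, the most similar model wins — this resolves converging
branches deterministically.

A top-to-bottom traversal cannot see an upward-growing lateral: it
surfaces in the images *above* its junction. So, after slice $n$ is done
and before moving to $n+1$, the tracker re-examines $n-1$, initialised
from the slice-$n$ objects. Anything recovered there that is not already
labelled was invisible from above: it becomes a *marker*. After the first
full pass, markers are consumed deepest-first; each spawns an upward pass
(which performs the mirror-image downward look, catching downward roots
reachable only through an upward segment), and passes alternate until no
pending markers remain. Termination is guaranteed: a marker requires
unlabelled pixels, voxels never become unlabelled, and every marker is
consumed exactly once. Only the first pass must traverse the whole stack —
its cost is exactly $2N-1$ slice-segmentation attempts for $N$ slices
(asserted as an acceptance property); marker passes end at target loss.

Each voxel records the direction of the pass that labelled it (1 down,
2 up; junction voxels keep the first-come label), which yields the
upward-growing fraction directly, and each consumed marker is a point
where growth direction changes.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.6 | data-vs-smoothness weight in $F$; published tomato settings are ≈ 0.61 |
| `beta` | 0.25 | minimum similarity for model replacement; ≈ 0.25–0.37 in published use |
| `bins` | 64 | histogram bins over the stack's global min–max; stable for 8- and 16-bit |
| `min_area` | 5 px | smallest surviving cross-section; below it, target loss |
| `band_width` | 6 px | window margin around a tracked object |
| `annulus_width` | 5 px | background-annulus width |
| `hist_smooth` | 1.5 bins | Gaussian sd for histogram smoothing before $p_{\mathrm{root}}$ |
| `max_iter` | 200 | per-evolution iteration cap |
| `connectivity_2d` | 8 | in-slice adjacency (8 keeps thin diagonal roots intact) |
| `overlap_threshold` | 1 px | labelled-overlap at which a look-back component counts as "seen" |
| `smooth_sigma` | 1 voxel | indicator smoothing before surface meshing |
| `mc_samples` | 10⁶ | Monte Carlo samples for hull volume |
| `rng_seed` | 1 | seeds the Welzl shuffle and Monte Carlo only |

Numerical choices that deserve justification:

* **Histogram smoothing** (`hist_smooth`). A root cross-section of ~15
  pixels cannot populate the ~10 bins its intensity noise spans; the raw
  ratio $h_r/(h_r+h_b)$ then starves the region of support and the
  tracker dies mid-root (observed directly during development). Smoothing
  both histograms with a 1.5-bin Gaussian is the minimal, standard
  repair and is exposed in the configuration.
* **Seed initialisation.** The annulus around the initial 3-pixel seed
  disc can lie wholly inside a thick root, making background look like
  root. `init_from_click()` therefore iterates grow → re-record histogram
  → re-estimate annulus until the pixel set stabilises (at most 6
  rounds). A seed on uniform background yields a small wandering region
  with a near-background histogram — deterministic, and returned to the
  caller unless it stays below `min_area`, in which case the seed is
  rejected with an error.
* **Marker compactness gate.** The minimal marker rule — "component with
  zero labelled overlap" — is one-shot: an upward branch diverging at
  less than a pixel per slice can be bridged to the labelled root by a
  single organic-noise voxel on the only slice where the rule could fire,
  silently dropping the whole upward subtree (we observed this at one
  render seed in seven). The implemented rule also splits partially
  overlapping components into their unlabelled remainders and accepts a
  remainder as a marker when it has at least `min_area` pixels *and*
  contains a 2×2 solid block. The block test separates genuine
  cross-sections (any disc of radius ≥ 1.5 px contains one) from the
  1-pixel-thin jitter arcs that boundary re-segmentation produces;
  full-scale phantoms without upward roots yield zero markers across
  seeds.
* **Marker order.** "Lowest in the stack first" is read physically:
  deepest slice (largest index) first, then creation order. At
  consumption a marker whose unlabelled remainder has dropped below
  `min_area` (a later pass claimed it) is discarded.

## Trait measurements

* **Volume** is exact: voxel count × (voxel size)³.
* **Surface area** sums triangle areas of an iso-surface at level 0.5.
  Meshing the *raw* binary indicator over-estimates smooth surfaces by
  ~8–9 % regardless of resolution (the staircase is chamfered, not
  smoothed — we measured 1.085 × 4πr² for a radius-20 ball with a
  reference marching-cubes implementation, outside this package's own 4 %
  validation band). The mask is therefore smoothed with a 1-voxel
  Gaussian first (`smooth_sigma`, 0 restores the raw behaviour), then
  triangulated by 6-fold tetrahedral decomposition with linear edge
  interpolation — chosen over table-based marching cubes as equally
  standard, free of the 256-entry case table, and easier to verify. The
  measured ball error is then −0.3 % at r = 20 and −2.1 % at r = 10
  voxels. The volume is zero-padded so the surface closes at stack
  boundaries, and one number is reported for the whole system.
* **Maximum width** is the diameter of the exact minimum enclosing circle
  (Welzl's randomized incremental algorithm) of the projected voxel
  centers; the shuffle is seeded but the circle is unique, so the result
  is seed-invariant. Voxel centers sit at (index − 1) × voxel size; the
  half-voxel rim is deliberately ignored (≤ 1 voxel effect). Above 500
  points the input is first reduced to its convex hull, which cannot
  change the circle.
* **Convex-hull volume** builds the hull of boundary-voxel centers
  (interior voxels are convex combinations of their axis neighbours, so
  dropping them is lossless) with QuickHull, and reports the Monte Carlo
  estimate hits/n × bounding-box volume, alongside the exact fan
  decomposition used by the tests. Degenerate (coplanar/collinear) masks
  give 0 with a warning.

## The phantom's stated world

`builtin_phantoms()` rasterises branched centerlines (swept balls,
linearly tapering radius, 0.5-voxel sampling; junction voxels belong to
the parent) into a 128 × 128 × 200 column at scale 1 and renders:

* root voxels $\sim \mathcal N(\mu(z), 8)$ with $\mu$ drifting linearly
  from 150 (top) to 110 (bottom) — the depth drift the tracker must adapt
  to;
* soil: 15 % near-black pores, 2 % *organic* voxels drawn from the root
  distribution at their depth (the root/soil overlap that defeats
  thresholds; `organic_fraction` is the difficulty dial, and Dice
  degrades monotonically in it by test), remainder
  $\mathcal N(80, 12)$ mineral;
* everything i.i.d. per voxel, fully determined by `rng_seed`; an
  optional Gaussian blur models partial-volume effects but defaults off
  so tests separate algorithmic from imaging error.

What a green test does establish: the tracker follows drifting, branching,
noise-embedded roots, recovers upward laterals the forward pass provably
misses (≥ 99 % of them at 2 % organic fraction), and reports calibrated
geometry. What it does not: performance on textured, aggregated real
soils (i.i.d. noise has no spatial structure), partial-volume boundaries,
scanner artefacts (beam hardening, rings), or roots thinner than ~1.5
voxels. Absolute trait values from the published tomato scans are not
reproducible — the scans are not deposited — which is why validation is
property-based plus the percent-change statistics recomputable from the
published table.

## Known limitations

* A lateral that shadows its parent (separation ≪ 1 px/slice for many
  slices) is merged by the in-slice connected-component logic; the
  look-back cannot mark what never separates. The `fig2_like` phantom's
  sub-lateral diverges perpendicular to its parent's drift for this
  reason.
* Appearance models are replaced, not blended, on update; a single
  unreliable-but-accepted observation can redirect a branch's model
  (mitigated by $\beta$).
* One seed, one plant: multi-plant scans need one run per seed point.
* The level-set variant is a faithful re-design from the published
  description (two parameters, local, appearance-driven), not a
  numerical transcription of the original implementation; absolute
  voxel-level agreement with that tool is out of scope.
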