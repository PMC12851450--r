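---
title: "An anatomy-biased lattice model of glioblastoma growth and its ABC fitting machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An anatomy-biased lattice model of glioblastoma growth and its ABC fitting machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomalatt)
```

## The model

Glioblastoma cells do not invade brain tissue isotropically: they migrate
preferentially along white-matter tracts (most prominently the corpus
callosum) and along blood vessels (perivascular invasion).  `gliomalatt`
implements a stochastic cellular automaton that captures exactly this
anisotropy and nothing more — no nutrient fields, no necrosis, no
angiogenesis — so that the entire phenotype is controlled by four
interpretable parameters.

Cells live on a 3D lattice whose voxels (default edge length 43 µm) each
hold at most `K` cells (default `K = 3`).  At every time step, the `N_t`
cells alive at the start of the step are processed in a uniformly random
permutation.  Each cell

1. **proliferates** with probability `p_p`, provided its voxel holds fewer
   than `K` cells.  The offspring is placed in the same voxel and is inert
   for the remainder of the step (it acts from the next step on);
2. **attempts one migration** with probability `p_m`, moving to one of its
   six face neighbors (the von Neumann neighborhood).  The attempt is
   aborted — the cell stays put — if the target voxel is full, outside the
   grid, or outside the brain mask.

The migration direction is drawn from a mixture of three distributions,

$$
\mathbf{p} \;=\; \tfrac{1}{6}\,(1 - w_{wm} - w_{bv})\,\mathbf{1}
\;+\; w_{wm}\,\mathbf{P}_{wm} \;+\; w_{bv}\,\mathbf{P}_{bv},
$$

where $\mathbf{P}_{wm}$ and $\mathbf{P}_{bv}$ are the attraction
distributions toward white matter and vasculature and the weights satisfy
$w_{wm} + w_{bv} \le 1$; the remainder is isotropic.  To build
$\mathbf{P}_{wm}$ for a cell, every white-matter voxel within Euclidean
distance `d` (default 5 voxels, inclusive; the cell's own voxel is excluded
because the direction to it is undefined) contributes the unit vector
pointing toward it.  Each unit vector is folded onto the six axis slots
(+x, −x, +y, −y, +z, −z) by placing each component's *magnitude* in the slot
matching its sign — the only reading that always yields a probability vector
— and the summed contributions are L1-normalized.  If no structure voxel is
in range the distribution falls back to uniform (1/6 each), so the term
degrades to isotropy rather than 0/0.

Two numerical consequences of the masks being static are exploited
throughout: the attraction distribution of every voxel can be **precomputed
once per atlas** (`attraction_field()`), after which a migration draw costs
constant time; and simulations are **bit-reproducible** given a seed,
because every stochastic decision is drawn from a single seeded generator in
processing order.

Tumors are initialized as a sphere of radius 8 grid points (inclusive
Euclidean distance) with 3 cells per voxel — 2109 voxels, 6327 cells — at an
injection site inside the brain mask.

### Parameters at a glance

| parameter | meaning | prior / default |
|---|---|---|
| `p_m` | per-step migration probability | U(0, 1) |
| `p_p` | per-step proliferation probability | U(0, 0.015) |
| `w_wm` | white-matter attraction weight | U(0, 1), `w_wm + w_bv <= 1` |
| `w_bv` | vessel attraction weight | U(0, 1), `w_wm + w_bv <= 1` |
| `K` | carrying capacity (cells/voxel) | 3 |
| `T` | steps per simulation | 1800 |
| `d` | sensing radius (voxels) | 5 |

The per-step probabilities become physical rates through the duration a
simulation represents: with 1800 steps spanning 90 days, one step is 1.2 h,
and `rescale_parameters()` converts `p_m` to µm/h and `p_p` to 1/day.

## Synthetic anatomy

Real vascular and diffusion-tensor atlases are not bundled; instead
`generate_synthetic_atlas()` produces a deterministic (seeded) stand-in
that elicits the same growth phenotypes: an ellipsoidal brain mask, white
matter as unions of slabs and dome-like spherical shells (a
corpus-callosum-like arc), and vasculature as branching capsule trees that
taper from a 2.5-voxel trunk radius down to capillary-scale 1-voxel tubes.
White matter can also be derived from a fractional-anisotropy volume via
`threshold_fa()` (inclusive cutoff, conventionally 0.5).  What the generator
does **not** emulate: anatomically faithful tract geometry, vessel density
gradients, tissue heterogeneity, or registration error between modalities.
Tests passing on synthetic anatomy therefore validate the algorithms, not
the biology of any particular brain.

Explicit geometry specifications that extend beyond the grid are clipped
with a warning; the auto-generated default anatomy clips silently, since its
trees are random and clipping at the skull is expected.

## Geometric summary statistics

Fitting compares a simulated slice against a segmented tumor image through
an 8-component, location-free descriptor: number of 8-connected components,
mean and SD of region area, mean and SD of region eccentricity, SD and
maximum of region perimeter, and maximum filled area.  Overlap measures such
as the Jaccard index score two interleaved checkerboards as completely
different (index 0) although they are morphologically identical; the
geometric descriptor is immune to this and to any misregistration, because
none of its components depends on position.

Conventions that were open and are now fixed (and bit-stable in tests):

- **Standard deviations** are population SDs (divide by *n*), so a
  single-region image has zero spread rather than `NA`.
- **Perimeter** uses the weighted border-configuration estimator classically
  used by region-property tools: each border pixel contributes 1, √2, or
  (1+√2)/2 according to its local configuration of border neighbors.
- **Eccentricity** comes from the normalized second central moments with the
  +1/12 per-pixel correction, so a single pixel is a circle (eccentricity
  0), not a degenerate case.
- **Filled area** fills holes found as background components (4-connectivity)
  not connected to the image border.
- **Empty images** map to the all-zero statistic vector so extinct tumors
  remain rankable.
- **Distances** between statistic vectors are Euclidean after standardizing
  each component by its median absolute deviation over the simulation pool
  (floored at 1e-9); the components span orders of magnitude, and a raw
  Euclidean norm would be dominated by the area terms.  A consequence is
  that acceptance thresholds are only comparable within one pool.

## ABC fitting

`abc_fit()` implements rejection ABC: simulate a pool of parameter sets
drawn from the priors (one simulation per set — the posterior absorbs the
model's stochasticity), rank by distance to the observation, and keep the
closest fraction (1% of 5000 at full scale).  The largest accepted distance,
δ, doubles as an inverse measure of fit quality and as the kernel bandwidth
for the **regression adjustment**: each parameter is logit-mapped to its
prior range, regressed on the standardized statistic discrepancies by
weighted least squares with Epanechnikov weights $1 - (d_i/\delta)^2$, and
shifted to the regression value at the observed statistics.  The logit
back-transform guarantees adjusted samples stay strictly inside their prior
ranges.  Three corner cases are handled explicitly: δ = 0 (perfect matches)
returns the accepted samples unchanged; rank-deficient designs zero the
unidentifiable directions (and a fully degenerate weighting falls back to
the unadjusted samples with a warning); and adjusted `(w_wm, w_bv)` pairs
that leave the simplex — which the per-parameter transform cannot prevent —
are projected back radially, with a message reporting the count.

Point estimates smooth the (adjusted) sample with an Epanechnikov kernel of
bandwidth 1/10 **on the range-normalized scale** — so the bandwidth means
the same thing for `p_p` (range 0.015) as for `p_m` (range 1) — truncate and
renormalize to the unit interval, and report the mean of the resulting
density with its 10%/90% density quantiles (sample quantiles are stored
alongside).

Two model variants can be compared: the full model and a white-matter-only
model (`w_bv` fixed at 0, the other three priors unchanged).
`model_support()` pools equal-sized simulation sets from both variants,
computes one common standardized distance, and reports the fraction of the
accepted set contributed by each variant — the ABC analogue of posterior
model probability.

### The `(w_wm, w_bv)` prior

The priors are independent uniforms subject to `w_wm + w_bv <= 1`.  We
sample by rejection (redraw violating pairs), which makes the joint density
uniform on the admissible triangle with marginal means 1/3; truncating one
coordinate given the other would have weighted the corners differently, and
nothing in the model argues for that.

## The scaled-down benchmark

`run_benchmark_study()` replays the synthetic estimator comparison: 16
ground-truth tumors at every low/high corner of
`p_m ∈ {0.2, 1}`, `p_p ∈ {0.0005, 0.005}`, `w_wm ∈ {0.1, 0.45}`,
`w_bv ∈ {0.1, 0.45}`, each fitted with (i) Jaccard distance, direct, (ii)
geometric distance, direct, (iii) geometric distance with regression
adjustment, scored by the mean over accepted (or adjusted) sets of the
absolute relative error averaged over the four parameters.

Problem sizes were fixed once at desk scale: a 64³ atlas at 43 µm, 300 steps
from a radius-4 seed sphere (771 cells), a single shared pool of 400 prior
simulations, and a 5% acceptance fraction (20 accepted per case).  Sharing
one pool across the 16 cases is statistically legitimate — the pool is drawn
from the prior independently of every observation — and is what makes the
study cheap; each case still ranks all 400 simulations.  At this scale the
absolute error magnitudes are atlas- and scale-dependent and are not
comparable to a full-size study; the *ordering* of the three methods is the
reproducible claim, and the test suite asserts it case-by-case (adjustment
must win on at least 12 of 16 cases against each direct method).

## Treatment sweeps

`run_treatment_sweep()` mimics a two-drug in-silico experiment: grow
untreated for 30 days, treat for 60, and compare against an untreated
90-day control run with the same seed.  A mix parameter `q_mig` sweeps from
1.0 (pure anti-migration) to 0.0 (pure anti-proliferation) in steps of 0.1;
each acting cell independently re-draws, every step, which mechanism is
blocked: migration with probability `q_mig`, otherwise proliferation.  (The
drug description could also be read as a conditional cascade per attempt;
we implement the mechanism-assignment reading, drawn per cell per step.)
Outcomes are the treated/control ratios of total cell count and of the
convex-hull volume of occupied voxel centers — the hull captures spatial
spread, which the count does not.  Degenerate hulls (coplanar or smaller)
have volume 0, and a sham arm on the control's seed stream yields ratios of
exactly 1, which the tests assert.  The day-to-step mapping is fixed at 20
steps/day (1800 steps ↔ 90 days).

## Numerical and design notes

- **Convex hull volumes** are computed by an incremental hull with exact
  64-bit integer orientation predicates (voxel centers are integer
  coordinates), so coplanarity decisions are never subject to floating-point
  noise.
- **Carrying-capacity checks** during proliferation count newborns already
  placed this step, so a voxel can never exceed `K` mid-step.
- **Tie-breaking** at the rejection boundary is by simulation index (stable
  sort), making accepted sets reproducible.
- **Acceptance counts** are `round(accept_frac * n)`; the rejection step is
  invariant under any strictly monotone transform of the distance.
- Simulation pools derive one sub-seed per simulation from the pool seed, so
  a pool is reproducible as a whole and each member individually.

## Known limitations

The model omits mechanisms named as extensions — nutrient limitation,
hypoxia, adhesion, chemotaxis, subclonal heterogeneity — and the synthetic
anatomy is a geometric caricature.  Slice choice is part of the experiment
specification, not inferred.  The distance standardization ties δ values to
their pool, so they are not comparable across pools or to thresholds
reported for other data.  Finally, with a single simulation per parameter
set, ABC conflates model stochasticity with parameter uncertainty by
design; increasing the pool size sharpens the posterior but does not remove
this conflation.
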