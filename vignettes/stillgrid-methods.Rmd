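---
title: "Grid-search optimization of spot finding for still-shot crystallography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-search optimization of spot finding for still-shot crystallography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stillgrid)
```

## The problem

Serial crystallography records one still exposure per crystal (or crystal
volume).  Each image is a zero-rotation snapshot: a reflection is recorded
only if its reciprocal-lattice node happens to graze the Ewald sphere, and
it is recorded *partially* — the node is sampled wherever the sphere cuts
it.  Sample delivery makes the image stream extremely heterogeneous: spot
size, spot count, background and crystal quality vary image to image, and
up to 90% of frames may contain no diffraction at all.

Indexing of a still is very sensitive to the parameters of the upstream
spot finder, chiefly the minimum peak height (in units of the background
standard deviation) and the minimum spot area (connected pixels).  A
single parameter pair that indexes one image well can fail outright on
the next.  `stillgrid` therefore optimizes the pair *per image*: it runs
the full spot-find → index → refine → estimate-mosaic → predict →
integrate pipeline at every point of a small parameter grid and keeps the
best result, judged by a physically motivated volume metric.

## The crystal model

Each still is fitted with a target-cell crystal model: known unit cell,
unknown orientation, plus two mosaic parameters.  The mosaic block size
$D$ (angstrom) sets the base diameter of a reciprocal-lattice point,
$\alpha \simeq 2/D$; the mosaic rotational spread $\eta$ (radians, full
width) makes points grow with distance $1/d$ from the reciprocal origin.
The full-width spot diameter at resolution $d$ is

$$ w(d) = \frac{2}{D} + \frac{\eta}{d}. $$

A node diffracts when it lies within $w(d)/2$ of the Ewald sphere.  The
**Ewald proximal volume** (EPV) is the reciprocal-space volume satisfying
that condition out to a fixed resolution limit $d_L$.  In spherical
coordinates about the Ewald sphere center ($r$ = radius, $\tau = 2\theta$
the scattering angle, $\kappa$ the azimuth about the beam),

$$ V = \int_0^{2\pi}\!\!\int_0^{\tau_{max}}\!\!
   \int_{1/\lambda - w/2}^{1/\lambda + w/2} r^2 \sin\tau \; dr\, d\tau\, d\kappa,
   \qquad \tau_{max} = 2 \arcsin\!\frac{\lambda}{2 d_L}, $$

with $w$ evaluated at the resolution $d = \lambda / (2\sin(\tau/2))$ that
the angle $\tau$ reaches.  The $\kappa$ and $r$ integrals are exact (a
$2\pi$ factor and a difference of cubes); the $\tau$ integral has no
convenient closed form and is evaluated by Gauss–Legendre quadrature
(`compute_epv()`, 128 nodes by default, converged to well below $10^{-6}$
relative; the test suite checks it against an independent Monte-Carlo
rejection-sampling volume oracle).  The expected number of reflections an
ideal detector would record is $N_{spot} = V \cdot V_{cell}$, because the
reciprocal lattice carries one node per volume $1/V_{cell}$
(`expected_spot_count()`); the synthetic generator and the prediction
module reproduce this relation to a few percent when averaged over random
orientations, which is the package's main internal consistency check.

A *smaller* EPV at equal coverage of the observed spots means a sharper
crystal model.  That ranking is what the grid search exploits.

## The grid search and the two-step selection

`build_grid()` enumerates all pairwise combinations of spot height and
spot area from a median and symmetric spread in unit steps (heights
$\le 0$ and areas $< 1$ are dropped).  The well-known worked example — a
height median of 8 ± 7 sigma and an area median of 12 ± 10 px — produces
a 15 × 21 = 315-point grid.

For one image, `fit_still()` runs the full pipeline at every grid point;
any stage may fail, and per-point failures are recorded as data.  From
the pool of completed integration results the best one is chosen in two
steps (`select_best()`):

1. keep the `ceiling(0.25 * N)` results with the smallest EPV
   (`ceiling` so that one result always survives);
2. among those, return the result with the most strong reflections,
   $I/\sigma(I) > 5$ (strict inequality; threshold configurable).

Ties are broken deterministically (EPV, then reflection count, then grid
order), so the selection is invariant under permutation of the pool — a
property the test suite checks by shuffling.

## Pipeline internals and numerical choices

* **Background / spot finding.** Per-pixel background level and sigma
  come from tile-wise median / scaled-MAD statistics (64 px tiles),
  robust to the sparse Bragg pixels and hot pixels.  Spots are maximal
  8-connected components of pixels at least `min_height` sigmas above
  background, kept if they span at least `min_area` pixels.  One
  background estimate per image is shared by all grid points; the two
  searched parameters do not interact with it.
* **Indexing** (`fit_orientation()`) is target-cell based: a
  deterministic low-discrepancy set of candidate orientations
  (Halton-sequence Shoemake quaternions, 140 000 by default, a ~2.5
  degree covering of the rotation group) is scored on difference vectors
  between the lowest-resolution spots — differences cancel any constant
  q error from a mis-stated beam center — and the best 80 candidates are
  polished by iterating nearest-node assignment with a Kabsch
  (orthogonal Procrustes) update.  A few fixed-point steps translate the
  beam center along the mean q residual, which recovers deliberate
  beam-center offsets of a couple of pixels.  Success requires half the
  spots within 0.15 of the shortest reciprocal cell edge.  Unknown-cell
  autoindexing is out of scope.
* **Refinement** (`refine_lattice()`) minimizes pixel-space
  observed-minus-predicted positions over a small rotation, the three
  cell lengths and the beam center (BFGS); a guard returns the input
  model if the rmsd would increase.
* **Mosaic estimation** (`estimate_mosaic()`) uses a coverage criterion:
  among scanned $\eta$ values (33 points over [0, 0.02] rad), with the
  minimal feasible $1/D$ per $\eta$ such that every strong indexed spot
  lies within $w(d)/2$ of the sphere, the pair with the smallest EPV is
  returned (ties toward smaller $\eta$).  If nothing covers, the scan
  boundary is returned flagged saturated.  This is a documented
  substitute for a full post-refinement of mosaic parameters; EPV values
  are computed from these post-fit parameters.
* **Integration** is plain summation in a fixed 3 px circular mask,
  background subtracted, with counting-statistics sigmas; predictions
  off the detector or touching masked pixels are dropped and tallied.

## The synthetic generator

There is no public still-image corpus bundled with the package, so every
claim is exercised on synthetic stills with known ground truth
(`random_crystal()`, `render_still()`, `generate_dataset()`).  A frame is
rendered by enumerating reciprocal nodes with $d \ge d_{min}$, keeping
those within $w(d)/2$ of the sphere, and drawing each as an isotropic 2-D
Gaussian on the detector whose integrated intensity is the full
reflection intensity (lognormal heterogeneity) times a partiality factor.
The partiality profile is a Gaussian falloff
$\exp(-\Delta r^2 / 2\sigma_r^2)$ with $\sigma_r = w/2.355$, i.e. full
width at half maximum $w$, so partiality is exactly 1/2 at the rendering
cutoff $|\Delta r| = w/2$; the profile shape is this package's choice —
any smooth monotone falloff tied to $w$ serves the purpose of testing.
Poisson noise is applied to background + signal; detector gain is fixed
at one count per photon and read noise is out of scope.  Orientations
are drawn uniformly over the rotation group via the Shoemake quaternion
map; one master seed yields per-image seeds drawn up front, so datasets
are byte-identical on re-run regardless of processing order.

Default study conditions (chosen once as representative of a moderately
heterogeneous serial experiment, and used by the test suite): a
tetragonal lysozyme-like cell 79.1 × 79.1 × 38.4 angstrom on a 400 × 400
px virtual detector (0.1 mm pixels, 50 mm distance, 1.3 angstrom
wavelength, 3.5 angstrom resolution limit), background 20–30 counts,
mosaic blocks 150–900 angstrom, mosaic spread 0.5–6 mrad, spot footprints
0.4–2.2 px and mean reflection intensities 120–8000 counts.  Two
orthorhombic forms with cells 69.1 × 171.6 × 146.9 and
69.6 × 171.1 × 291.9 angstrom (a near-exact doubling of *c*) exercise
the clustering and Bravais-filter paths.  What the generator does *not*
emulate — detector panel gaps, spectral bandwidth, polarization,
absorption, non-Gaussian point-spread, correlated noise — bounds what
passing tests show about real data: they validate the algorithms and
their contracts, not detector-specific robustness.

The parameter-recovery fixture uses well-ordered crystals (D
1500–3000 angstrom, eta 0.3–1 mrad) rendered noiselessly: sharper
reciprocal nodes give sparser, cleaner spot lists, which is the regime
in which recovered orientations and cells can be compared against ground
truth at the 0.5 degree / 0.5 percent level.  The grid-search dispersion
fixture deliberately spans the opposite regime (weak, sharp spots) where
the choice of spot-finding parameters genuinely decides which marginal
spots enter the fit.

## Triage, preprocessing, analytics

Frames are recentered by symmetric zero-padding (data pixels are never
cropped; padded pixels are zero and masked), beam-stop shadows are
masked as a disc plus rectangular arm, and blank images are triaged by a
single cheap spot-finder pass: an image is kept iff it has at least
`min_spots` candidate spots (default 10 — the choice is exposed because
no canonical value exists; `min_spots = 0` bypasses triage).

After a run, integrated images are clustered by unit cell: cells are
Niggli-reduced (Krivy–Gruber algorithm) and compared with a Euclidean
metric on reduced edges plus angles scaled by 0.5 angstrom/degree — an
explicit simplification of the Andrews–Bernstein G6 distance, adequate
to separate a doubled axis while keeping sub-percent cell noise together
(average linkage, cut at 5.0 by default; the full G6 metric is an
upgrade path).  The dominant cluster (most members, ties to the lower
index) feeds a key=value downstream-parameter stub listing its images,
centroid cell and the lowest-symmetry Laue class of the Bravais lattice
(fixed table; e.g. P4/m for tetragonal P, P-3 for hexagonal P whose
lattice also hosts trigonal groups).  Run summaries report the image
accounting (total / no diffraction / not integrated / failed filter /
per cluster), a refined beam-center scatter table, a per-image limiting
resolution histogram (taken as the highest-resolution integrated
reflection, one documented choice among several defensible ones) and
the selected-grid-point heat map.

## A small worked run

```{r example, eval = FALSE}
det <- detector_geometry(400, 400, 0.1, 50, c(200.5, 200.5))
truth <- random_crystal(c(79.1, 79.1, 38.4, 90, 90, 90),
                        D_range = c(500, 500), eta_range = c(0.002, 0.002),
                        rng_seed = 42)
still <- render_still(truth, det, background_mean = 20, d_min = 3.5,
                      rng_seed = 42)
fit <- fit_still(still$frame, target_cell = c(79.1, 79.1, 38.4, 90, 90, 90),
                 grid = build_grid(4, 1, 5, 2))
print(fit)
coef(fit)
```

## Problem sizes and limitations

The test-suite fixtures use 50-image runs on 3 × 5 or smaller grids and
a 400 × 400 px detector; these sizes were chosen so that a complete
check of every property runs comfortably on a laptop while still
exercising hundreds of full pipeline executions.  Larger grids (the
315-point worked example) and larger detectors are supported but scale
linearly in grid points × images.

Known limitations: indexing requires a target cell; Bravais assignment
is a reduced-cell tolerance test, not symmetry scoring; integration is
summation only (no profile fitting); the EPV tie between very large D
and very small eta is weakly identifiable on sparse spot lists, so
mosaic parameters should be read as a covering model, not as physical
measurements; and post-refinement, scaling and merging are deliberately
out of scope.
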