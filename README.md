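# stillgrid

Per-image optimization of spot-finding parameters for still-shot serial
crystallography, with selection of the best integration result by the
Ewald proximal volume (EPV) metric.

## Why

In serial crystallography every crystal contributes a single still
exposure.  Whether a still can be indexed and integrated at all is
extremely sensitive to the two spot-finder thresholds — the minimum peak
height (in background-sigma units) and the minimum spot area (connected
pixels) — and no single pair works across a heterogeneous image set.
`stillgrid` searches a grid of all pairwise combinations of the two
parameters *for each image*, runs a full spot-finding → target-cell
indexing → lattice refinement → mosaic estimation → prediction →
integration pipeline at every grid point, and selects the best result.

The selection uses the crystal mosaic model: block size *D* gives a base
reciprocal spot diameter 2/*D*, rotational spread *eta* grows spots with
distance 1/*d* from the origin, so the full spot width is
*w(d) = 2/D + eta/d*.  The EPV is the reciprocal-space volume within
*w(d)/2* of the Ewald sphere out to resolution *d_L*,

    V = ∫∫∫ r² sin(tau) dr dtau dkappa ,
        r in [1/lambda − w/2, 1/lambda + w/2],
        tau in [0, 2 arcsin(lambda / 2 d_L)],  kappa over the full circle,

evaluated by quadrature in tau (the other two integrals are exact), and
*N*<sub>spot</sub> = EPV · *V*<sub>cell</sub> is the ideal-detector
reflection count.  The best grid point is chosen in two steps: (i) keep
the 25% of integration results with the smallest EPV, (ii) among those
take the one with the most strong reflections (*I*/σ(*I*) > 5).

The package also provides a synthetic still generator with known ground
truth (SMV files + manifest), beam recentering and beam-stop masking,
blank-frame triage, Niggli-reduction-based unit-cell clustering with
dominant-cluster marking, Laue-class selection, and run-level analytics
(parameter heat map, beam-center scatter, summaries).

## Worked example

```r
library(stillgrid)

cell <- c(79.1, 79.1, 38.4, 90, 90, 90)          # tetragonal, lysozyme-like
det  <- detector_geometry(400, 400, 0.1, 50, c(200.5, 200.5))
truth <- random_crystal(cell, D_range = c(500, 500),
                        eta_range = c(0.002, 0.002), rng_seed = 42)
still <- render_still(truth, det, background_mean = 20, d_min = 3.5,
                      rng_seed = 42)

fit <- fit_still(still$frame, target_cell = cell,
                 grid = build_grid(4, 1, 5, 2))   # 3 heights x 5 areas
print(fit)
#> still grid-search fit [sim_seed42]: 15/15 grid points completed
#>   best point: height 3 sigma, area 3 px; 262 reflections, 262 strong, EPV 0.001057
round(coef(fit), 4)
#>         a         b         c     alpha      beta     gamma         D       eta
#>   79.1065   79.1018   38.3894   90.0000   90.0000   90.0000  531.3789    0.0019
#> beam_slow beam_fast
#>  200.5054  200.5017
```

All 15 grid points complete on this clean image; the selected model
recovers the cell to better than 0.03%, the beam center to 0.01 px, and
the mosaic model (D = 531 angstrom, eta = 1.9 mrad) sits close to the
generating parameters (500 angstrom, 2 mrad).  The EPV printed is the
reciprocal-space volume of that model; smaller at equal spot coverage
means a sharper crystal model.  `predict(fit)`, `residuals(fit)` and `plot(fit)` expose the
predicted reflection table, the observed-minus-predicted spot positions
and an overlay image.

A dataset-level driver (`process_dataset()`) adds triage and returns a
run object for `cluster_cells()` / `summarize_run()`.  A thin CLI over
the same functions is in `inst/cli/stillgrid.R`
(`generate`, `triage`, `spots`, `process`, `analyze` subcommands).

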