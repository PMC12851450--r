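# gliomalatt

Glioblastoma invades the brain anisotropically: tumor cells migrate
preferentially along white-matter tracts and blood vessels. `gliomalatt`
implements a stochastic lattice (cellular-automaton) model of this growth in
3D brain anatomy, plus everything needed to *fit* the model to segmented 2D
tumor images and to run in-silico drug experiments on the fitted parameters.
It is aimed at computational oncologists and systems biologists who want a
small, fully reproducible, parameter-interpretable growth model rather than
a heavyweight PDE framework.

## The model in one paragraph

Cells occupy voxels (43 µm, carrying capacity `K = 3`) of a lattice masked
by a brain volume. Per time step, each cell proliferates with probability
`p_p` (if its voxel is below capacity; offspring are inert until the next
step) and attempts one von Neumann move with probability `p_m`, drawn from

```
p = (1/6)(1 − w_wm − w_bv) 1 + w_wm P_wm + w_bv P_bv ,
```

where `P_wm` / `P_bv` are the normalized sums of unit vectors toward every
white-matter / vessel voxel within sensing radius `d = 5`, folded onto the
six lattice directions. Fitting uses rejection ABC on an 8-component
location-free geometric descriptor of a binary tumor slice (component count,
area / eccentricity / perimeter moments, filled area) with local-linear
regression adjustment under an Epanechnikov kernel, and reports
kernel-density point estimates with 10 %/90 % percentiles. Per-step
probabilities rescale to physical rates (µm/h, 1/day) from the experiment
duration.

## Worked example

Fit the model to a tumor grown with known parameters on synthetic anatomy:

```r
library(gliomalatt)

atlas <- generate_synthetic_atlas(shape = c(64, 64, 64), seed = 42)
field <- attraction_field(atlas, d = 5)       # precompute per-voxel bias
init  <- initialize_tumor(atlas, radius = 4, cells_per_voxel = 3)

truth <- sim_params(p_m = 0.8, p_p = 0.004, w_wm = 0.4, w_bv = 0.2,
                    steps = 300)
obs   <- simulate_tumor(truth, atlas, init, seed = 7, field = field)
slice <- extract_slice(obs, axis = 3, index = 32)

draws <- sample_prior(400, seed = 1)
pool  <- simulate_pool(draws, atlas, init, steps = 300,
                       slice_index = 32, field = field, seed = 2)
fit   <- abc_fit(pool, slice, accept_frac = 0.05)
fit
```

```
<abc_fit> 400 simulations, 20 accepted (geometric distance), delta = 0.7808, regression-adjusted
# A tibble: 4 × 6
  parameter estimate     q10     q90 sample_q10 sample_q90
  <chr>        <dbl>   <dbl>   <dbl>      <dbl>      <dbl>
1 p_m        0.376   0.159   0.567      0.171      0.547
2 p_p        0.00362 0.00167 0.00516    0.00199    0.00478
3 w_wm       0.457   0.287   0.651      0.307      0.648
4 w_bv       0.181   0.0897  0.271      0.118      0.249
```

The attraction weights and the proliferation probability are recovered well
(truth 0.4 / 0.2 / 0.004); the migration probability is identifiable only
up to the spread visible in its wide 10–90 % interval — a single 2D slice
carries limited information about 3D motility. `delta`, the largest accepted
distance, is an inverse measure of fit quality. Converting the point
estimates to physical rates for a 90-day experiment:

```r
est <- tidy(fit)
rescale_parameters(est$estimate[est$parameter == "p_m"],
                   est$estimate[est$parameter == "p_p"],
                   duration_days = 90, spacing_um = 43, steps = 1800)
#>     p_m     p_p P_m_um_per_h P_p_per_day dt_hours duration_days steps
#> 1 0.376 0.00362         13.5      0.0723      1.2            90  1800
```

i.e. a migration rate of ~13.5 µm/h and a proliferation rate of ~0.07/day.

Other entry points: `run_benchmark_study()` (16-corner estimator
comparison: Jaccard vs geometric vs geometric+regression),
`model_support()` (full vs white-matter-only model comparison by pooled
acceptance fractions), `run_treatment_sweep()` (anti-migration /
anti-proliferation drug-mix curves with cell-count and convex-hull
readouts), `threshold_fa()` / `read_volume()` / `write_atlas()` (NIfTI IO),
and `autoplot()` methods for lattices, fits, and sweeps.

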