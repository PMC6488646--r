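# spherostress

Multicellular tumor spheroids accumulate **growth-induced solid stress**: as
cells proliferate inside the aggregate, elastic stress is stored in the
tissue even when no external load is applied. A partial incision releases
that stress — the cut gapes open, the compressed core swells into it — and
the size of the opening is a mechanical readout of how much stress was
stored. `spherostress` implements the complete quantitative pipeline around
this experiment for R users working on tissue biomechanics:

* a **forward mechanical model**: a plane-strain finite-element simulation of
  an incised spheroid cross-section made of a compressible
  Ciarlet–Geymonat hyperelastic material
  (`W = a(I₁−3) + b(I₂−3) + c(J²−1) − d·log J`, ν = 0.46, a′ = 0.4)
  carrying a spherically symmetric stored-stress field
  `σ_rr(r) = γ(1 − (r/R)ⁿ)` with the circumferential component fixed by
  mechanical equilibrium. Solving to equilibrium predicts the
  **relaxation index** `100 × opening / diameter` as a function of the
  incision depth — the model's response curve;
* a **stored-stress estimator**: for each magnitude γ on a grid, the
  fraction of measured spheroids whose relaxation index falls below the
  simulated response curve samples the cumulative distribution of the
  per-spheroid stored stress; fitting a Gaussian cdf `Φ((γ−μ)/σ)` to those
  samples yields the cohort's mean stored-stress magnitude and its spread;
* **Hertz–Sneddon AFM elasticity fitting**: apparent Young's moduli from
  approach force curves via `F = (2/π)·E/(1−ν²)·tan(α)·δ²` (conical tip,
  α = 17.5°, ν = 0.5), with Gaussian smoothing, contact-point estimation,
  and per-spheroid stiffness summaries compared by Mann–Whitney U;
* **morphometry and drug-response assays**: volume and flatness
  (shortest/longest principal semi-axis) of segmented voxel stacks, and
  irinotecan growth-inhibition statistics from projected-area time courses;
* **seeded synthetic-data generators** for all four input kinds, each
  carrying its ground truth, so every estimator is tested closed-loop.

All analysis functions take a data frame first and return tibbles, so the
pipeline composes with dplyr and the pipe; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` visualizations.

## Worked example: how much stress does a spheroid store?

Build the forward response surface once (72 equilibrium solves; about a
minute at the default mesh, a few seconds at `target_edge_length = 45`),
generate a synthetic cohort of 29 incised spheroids whose true per-spheroid
stress is Gaussian with mean 0.276 a.u., and recover that distribution from
the observable columns alone:

```r
library(spherostress)

surf   <- response_surface(target_edge_length = 45)
cohort <- generate_incision_cohort(29, stress_mean = 0.276,
                                   stress_sd = 0.037,
                                   surface = surf, seed = 1)
cohort[1:3, 1:5]
#>   spheroid_id diameter_um incision_depth_um opening_um depth_fraction
#> 1 synth-001          447.              259.       201.          0.579
#> 2 synth-002          465.              198.       176.          0.426
#> 3 synth-003          475.              243.       189.          0.512

est <- estimate_stored_stress(cohort, surf)
est
#> <stress_estimate> stored stress mu = 0.2818 +/- 0.0339 (a.u.), rss = 0.00323, 12 cdf samples
#>   regression-consistency gamma* = 0.2936
```

The fitted `mu = 0.282` recovers the generating mean 0.276 to well within
one generating standard deviation; `sigma = 0.034` is the inferred
population spread (in the same arbitrary stress units, normalized to the
material's shear modulus). `gamma*` is the independent cross-check: the
single magnitude whose response curve best tracks the cohort's
depth-versus-relaxation regression line. `autoplot(est)` shows the sampled
cdf points and the fitted Gaussian cdf.

The companion assays work the same way:

```r
map <- generate_force_map(1, young_modulus = 3000, seed = 1)
fit_sneddon(map$data[[1]], map$spring_constant[1])
#> <sneddon_fit> E = 3018 Pa, contact at 0.925 um, rms 1.19e-11 N, 219 points [ok]

ball <- generate_voxel_spheroid(c(100, 100, 30))   # flattened ellipsoid, um
shape_metrics(threshold_mask(ball, 50))
#>   volume_um3 flatness axis_long_um axis_mid_um axis_short_um n_voxels
#> 1   1256668.    0.300        100.0       100.0          30.0  3020656

mann_whitney(c(1, 2, 3), c(4, 5, 6))
#>   statistic p_value method
#> 1         0     0.1 exact enumeration
```

## Scope

The forward model is a 2D plane-strain cross-section through the incision
plane (the spherical stress-link formula is available for reporting);
quasi-static equilibrium only — viscoelastic transients, slit-face contact
and full 3D incised-sphere meshes are out of scope, as are vendor AFM file
formats and bright-field segmentation. See the methods vignette
(`vignettes/spheroid-biomechanics.Rmd`) for the model, its assumptions, and
the design decisions.
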