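---
title: "Quantifying growth-induced solid stress, stiffness and shape of tumor spheroids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying growth-induced solid stress, stiffness and shape of tumor spheroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherostress)
```

## The problem

A multicellular spheroid grown from a few hundred cells over several days
reaches the same volume as one assembled from thousands of cells in two
days, but not the same mechanical state: proliferation against the
constraint of the surrounding tissue stores elastic stress in the aggregate.
The classic way to reveal that stored (residual) stress is a partial
incision: if stress is present, the cut opens measurably — the compressed
core swells into the cut while the tissue boundary relaxes — and the
magnitude of the opening, normalized as the *relaxation index*
`100 × opening distance / spheroid diameter`, increases with both the
stored-stress magnitude and the incision depth.

Turning that observation into a number requires a forward mechanical model
(how much would a spheroid carrying stress γ open for a cut of depth d?) and
an inversion strategy (what distribution of γ across a cohort explains the
measured openings?). This vignette documents both, together with the
companion assays the package implements (AFM stiffness, voxel morphometry,
drug-response statistics) and the synthetic data that exercises them.

## Forward model

### Geometry and discretization

The simulated domain is the circular cross-section of the spheroid through
the incision plane: a 2D disk of radius R (default 225 µm, a 450 µm
spheroid) under plane strain. The incision is a straight radial slit
entering from the boundary along a diameter; a depth fraction of 0.5 reaches
the center, and the experimentally probed range 0.40–0.65 carries the slit
slightly past it. The mesh is a structured polar grid of linear triangles
with one ring snapped onto the slit tip; nodes on the slit are duplicated
into two faces (geometrically coincident by default) and the tip is a
single shared node, so the cut can open without remeshing. A full 3D
incised-sphere simulation would change the absolute response values but not
the structure of the inference, and is out of scope; the spherical variant
of the stored-stress field remains available for reporting
(`stored_stress_components(..., symmetry_mode = "spherical")`).

### Constitutive law

The tissue is a compressible Ciarlet–Geymonat hyperelastic solid,

$$W(F) = a\,(I_1-3) + b\,(I_2-3) + c\,(J^2-1) - d \log J,$$

parameterized by the small-strain Poisson ratio ν = 0.46 and the
dimensionless share parameter a′ = 0.4 through the canonical split
`a = a′µ/2`, `b = (1−a′)µ/2`, `c = λ/4 − b`, `d = 2a + 4b + 2c`, with the
shear modulus µ normalized to 1 so that all stresses (including γ) are in
units of µ. This map makes the linearized response carry exactly the Lamé
pair (µ, λ = 2µν/(1−2ν)) and the stress vanish identically at F = I; both
properties are verified numerically in the tests. An alternative
normalization that drops the I₂ term (b = 0) leaves the material three
times softer than its nominal µ; at the upper end of the working γ range
the stored stress then exceeds the shear stiffness and the compressed
regions of the disk lose stability (the Newton solver stalls at a genuine
limit point). The canonical split keeps γ/µ ≤ 0.45 over the whole working
range, where the solver is robust — that observation fixed this design
choice.

In plane strain the I₂ term collapses to I₁- and J²-terms
(`I₂ = I₁^{2D} + J²` when the out-of-plane stretch is 1), so the 2D solver
uses effective coefficients (a+b, c+b) without loss of generality.

### Stored stress and its coupling

The stored field is spherically (here: circularly) symmetric with a
power-law radial profile vanishing at the free surface,

$$\sigma_{rr}(r) = \gamma\left(1-(r/R)^n\right),
\qquad
\sigma_{\theta\theta} = \sigma_{rr} + \kappa\, r\,
  \frac{d\sigma_{rr}}{dr},$$

with κ = 1/2 for spherical and κ = 1 for plane symmetry — the unique
circumferential component making the field self-equilibrated
(zero divergence), which the tests verify to 10⁻⁸ on a 1000-point grid. The
exponent n is not constrained by the available data; n = 2 is the default
and is exposed in every interface.

Two sign conventions are possible and only one is physical. The reported
magnitude γ ≥ 0 parameterizes the component functions above, but
growth-induced stress is *compressive* in the core: the field entering the
solver is S₀ = −σ, i.e. σ_rr(0) = −γ. With the opposite sign the simulated
cut closes with interpenetrating faces at every γ — we measured this
directly — whereas with the compressive core the cut gapes at the mouth,
the core swells into it (mean det F > 1 in the inner third), and the
response is strictly increasing in both γ and depth, matching the
experiment qualitatively. Note one frame-dependent caveat: because the two
halves hinge apart about the anchored pole, outer-boundary points near the
mouth move outward in the laboratory frame; "boundary retraction" is
therefore not asserted as a literal decrease of radius.

The coupling is the simplest consistent with a stress present at rest in
the reference configuration: an additive first Piola–Kirchhoff pre-stress
pushed forward with the deformation, `P(F) = P_el(F) + F S₀`, which is the
gradient of the potential `∫ W(F) + ½ (F S₀) : F`. For the uncut disk this
field is in equilibrium and nothing moves; cutting releases the slit-face
tractions and the body finds a new minimum.

### Solver

Each equilibrium is solved by Newton's method on the discrete residual with

* incremental loading: γ ramped in 5 increments, with adaptive halving of
  any increment whose Newton loop fails (restarting from the last converged
  level);
* an Armijo backtracking line search on the total potential energy (whose
  gradient is the residual), guarded against element inversion
  (det F ≤ 0 rejected);
* relative residual tolerance 10⁻⁸ per load level, at most 30 iterations
  per level;
* rigid-body modes removed by pinning the boundary node diametrically
  opposite the slit mouth and the transverse motion of its inward
  neighbour.

At γ = 0 the reference state has an exactly zero residual, so the solver
returns a zero displacement and a zero relaxation index — the null test
that quantifies solver fidelity.

The default mesh resolution, `target_edge_length = radius/15` (15 µm),
changes the relaxation index by less than 1% under a further uniform
refinement at γ = 0.25, depth 0.5; the tests enforce the 2% criterion. The
relaxation index is dimensionless and exactly scale invariant (doubling R
and all lengths reproduces it to machine precision), so all simulated
responses transfer across spheroid sizes at fixed depth fraction.

### Response curves and the cached surface

`simulate_response_curve()` evaluates the relaxation index over a depth
grid at fixed γ; `response_surface()` does so over a 12 × 6 (γ, depth) grid
— γ uniform on [0.02, 0.45], depths 0.40 to 0.65 in steps of 0.05, the
experimental window — and the inference interpolates this surface
bilinearly, never extrapolating. The surface is deterministic and can be
cached to JSON keyed by its build parameters; the inference layer never
re-solves on a cache hit.

## Stored-stress inference

For a cohort of incision measurements (diameter, incision depth, opening),
each observation is reduced to (depth fraction, relaxation index). For each
γ on the grid, the fraction of observations lying at or below the response
curve at their own depth estimates P(stored stress ≤ γ), because the
forward response is monotone in γ: sweeping the grid samples the cdf of the
per-spheroid stored-stress magnitude. A Gaussian cdf Φ((γ−µ)/σ) is then
fitted by least squares, giving the cohort mean µ and spread σ.

Numerical choices, all of which the tests pin down:

* **Ties** count as "below" (≤, with a 10⁻⁹ slack so exact ties survive
  floating-point interpolation). Under measurement noise, exact ties are a
  measure-zero event, so this choice is inconsequential but deterministic.
* **No isotonic pre-processing**: raw count fractions are fitted even if
  non-monotone; the parametric cdf absorbs the noise.
* **Fit initialization**: µ at the interpolated half-crossing of the
  empirical cdf, σ at a quarter of the grid span; bounds keep µ inside the
  grid and σ in [10⁻⁴, span]. Levenberg–Marquardt is the primary optimizer
  with a bounded quasi-Newton fallback for step-like degenerate samples.
  On noiseless Gaussian samples the fit recovers (µ, σ) to 10⁻⁶ and agrees
  with a 200 × 200 brute-force lattice search within one cell.
* **Least squares, not binomial likelihood**: the sampled fractions are
  correlated across γ (the same cohort is reused), so neither criterion is
  the true likelihood; least squares is the transparent choice and the
  recovery experiments below measure what it delivers.
* The **regression-consistency check** (`gamma_star`) reproduces the
  simpler published readout: the single γ whose response-curve points lie
  closest to the cohort's ordinary-least-squares depth–relaxation line. It
  is reported alongside (µ, σ), never mixed into them.

## Synthetic data: what it emulates, what it does not

`generate_incision_cohort()` draws per-spheroid stress from a Gaussian
truncated to non-negative values (and to the response surface's γ support),
depth fractions uniform on [0.40, 0.65], diameters lognormal around 450 µm
(CV 5%), maps (γ, depth) through the same response surface the inference
uses, and adds Gaussian noise (SD 1 percentage point — a declared
assumption, the measurement noise of the real assay being unpublished) to
the relaxation index before back-computing the opening. Cohort sizes follow
the study's arms (19/29/22). Because generator and estimator share the
forward surface, closed-loop recovery isolates the inference machinery:
passing says the cdf sampling and fit are unbiased and well-calibrated at
these sample sizes, not that the forward model matches any particular real
spheroid. The truncation at zero slightly biases recovery when µ/σ is
small; at the study regimes (µ/σ ≈ 4.5–7.5) it is negligible.

At the two study regimes (n = 29 at µ₀ = 0.276, n = 22 at µ₀ = 0.166,
σ₀ = 0.037), the fitted µ lands within ±σ₀ of µ₀ in well over 90% of 100
seeded repetitions, and the median over repetitions agrees with µ₀ to
better than 1% — the quantities `scripts/acceptance.R` recomputes.

The AFM generator inverts the Sneddon law into deflection-vs-piezo approach
curves capped at 1 nN, with a flat pre-contact baseline and 0.3 nm additive
deflection noise (quiet liquid-cell conditions; the 1 nN cap implies a
maximum deflection of only ~7 nm at a 0.15 N/m spring constant, so noise
several times larger would not represent a usable instrument). The voxel
generator rasterizes solid ellipsoids on the microscope grid
(0.645 × 0.645 × 1 µm); it does not emulate clearing artefacts, intensity
gradients or surface texture. The dose-response generator suppresses an
exponential area growth rate by a Hill factor
`1 − I_max·cʰ/(cʰ + Kʰ)`; half-inhibition doses of 4 vs 12 µM reproduce the
"similar at low dose, divergent above 5 µM" pattern of drug response
between production regimes.

## Companion assays

**AFM elasticity.** Approach curves are smoothed with a discrete Gaussian
kernel (σ = 3 samples — the instrument convention "3 pixels" read as σ, not
FWHM), the baseline is the median of the leading 20%, and the contact point
is initialized at the first sample exceeding 5 noise SDs. The Young's
modulus and contact point are then fitted jointly: for each candidate
contact the modulus enters the Sneddon law linearly and is profiled in
closed form, leaving a 1D optimization over the contact point. Fits outside
[50 Pa, 1 MPa], without detectable contact, or with fewer than 10 usable
points are flagged and excluded from per-spheroid summaries (but counted).
Noiseless round trips recover E to 0.1% across 0.5–10 kPa; 5%
multiplicative force noise keeps E within 5% in ≥90% of repetitions.

**Morphometry.** Volume is voxel count × voxel volume, exactly. Flatness is
the ratio of shortest to longest principal semi-axis of the segmented
voxel cloud, with semi-axes √(5λᵢ) from the coordinate covariance — the
uniform-ellipsoid identity. This is a declared convention (the commercial
software's formula is not published); it yields ≈1 for spheres and
reproduces the target flatness of rasterized test ellipsoids to ±0.02,
including under anisotropic voxels. Segmentation keeps the largest
6-connected component after fixed thresholding, with no hole filling.

**Statistics.** The Mann–Whitney U test enumerates the exact null
distribution over all group assignments of the pooled midranks for combined
samples up to 16 (so ties are exact), and uses the tie-corrected normal
approximation without continuity correction beyond; the tests verify both
paths against an independent pair-counting enumeration oracle and the
reference implementation in base R.

## Problem sizes and defaults

| Quantity | Default | Why |
|---|---|---|
| Disk radius R | 225 µm | 450 µm spheroid diameter |
| Poisson ratio ν | 0.46 | nearly incompressible soft tissue |
| CG share a′ | 0.4 | published material parameterization |
| Profile exponent n | 2 | smooth core plateau; not data-constrained |
| Mesh edge | R/15 | <1% refinement change in relaxation index |
| γ grid | 12 on [0.02, 0.45] | covers both study regimes with headroom |
| Depth grid | 0.40–0.65 by 0.05 | experimental incision range |
| Load steps | 5 (adaptive) | robust at γ/µ ≤ 0.45 |
| Cohort noise | 1 %-point SD | declared assumption |
| AFM α, ν, F_max | 17.5°, 0.5, 1 nN | MLCT probe in liquid |
| Voxel size | 0.645 × 0.645 × 1 µm | light-sheet acquisition setting |

The test suite uses a coarser mesh (45 µm edges) for the shared response
surface — generator and estimator interpolate the same surface, so recovery
tests are mesh-independent by construction — and the full default mesh for
the convergence and acceptance-facing checks.

## Known limitations

* 2D plane strain, not 3D: absolute response values are specific to the
  cross-section model; inferred µ, σ are in model units (of the shear
  modulus) and comparable across cohorts, not absolute tissue stresses.
* No slit-face contact: at large γ the faces may interpenetrate locally
  near the tip in principle; in the working range the measured gaps are
  positive everywhere.
* Quasi-static equilibrium only; the measured 10 s/180 s openings are
  treated as equilibrium approximations.
* The Gaussian cdf fit treats sampled fractions as independent; they are
  not, and σ in particular inherits extra variance from measurement noise.
* The flatness formula is a stated convention, not the commercial one.
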