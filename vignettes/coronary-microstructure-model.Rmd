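---
title: "A microstructure-based model of passive and active coronary artery mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A microstructure-based model of passive and active coronary artery mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coromicro)
library(dplyr)
```

## The model and its assumptions

`coromicro` treats the coronary artery wall as an incompressible,
hyperelastic, two-layer thick-walled tube whose stress is assembled from the
measured geometry of its load-bearing constituents. The modelling
assumptions are:

* **Kinematics.** Deformations are axisymmetric, torsion-free and
  independent of axial position; transverse sections remain planar; the
  unique unloaded reference is the radially cut-open zero-stress sector
  (opening angle $\Theta$). Incompressibility then fixes the whole
  transmural deformation from two scalars: the loaded outer radius $r_o$
  and the axial stretch $\lambda_z$. All shear strain and stress components
  vanish under this loading, so tensors are diagonal in the cylindrical
  $(\theta, r, z)$ basis.
* **Fluid-like ground substance and affine fibers.** The non-fibrous matrix
  contributes only a hydrostatic pressure $p$; each fiber deforms affinely
  with the continuum, so its uniaxial strain is
  $e = \mathbf{E} : \mathbf{N}\otimes\mathbf{N}$ for reference direction
  $\mathbf{N}$. The hydrostatic multiplier never enters the measurable
  quantities — luminal pressure, axial force and stress *differences* are
  all assembled from the constitutive "extra" stresses, and the traction
  condition $\sigma_{rr}(r_o) = 0$ pins the profile.
* **Tension-only fibers.** Elastin and collagen carry no compression or
  bending; the switch is applied per fiber inside the orientation integral,
  not to the layer tensor.
* **Layered microstructure.** The media (inner fraction of the wall,
  default 2/3 of the reference thickness) carries mirrored
  truncated-normal elastin/collagen and SMC families about the
  circumferential axis plus an isotropic inter-lamellar (IL) elastin
  network in the circumferential–radial plane; the adventitia carries
  bimodal truncated-normal mixtures of elastin and collagen (one
  near-circumferential and one near-longitudinal family). Fiber material
  properties are uniform across layers.
* **Active SMC law.** Contraction is phenomenological: a skewed parabola in
  the cell-axis stretch peaking at $\sigma_{max}$ when
  $\lambda = \lambda_{max}$, a transverse response scaled by $\tau$, and a
  linear radial law. Mechano-chemical cross-bridge kinetics and
  length-history dependence are out of scope.

## Parameters

Material parameters (defaults are the refined-fit averages for porcine LAD
coronary arteries; all stresses in MPa):

| parameter | meaning | default |
|---|---|---|
| `k_IL` | IL elastin stiffness | 0.18 |
| `k_E`  | planar elastin stiffness | 0.27 |
| `k_C`, `M_C` | collagen power-law coefficient / exponent | 29.5, 5.23 |
| `rho1`, `rho2` | active-law curvature and skewness | 0.31, 1.43 |
| `lam_max`, `sigma_max` | optimal SMC stretch and peak stress | 1.34, 0.09 |
| `tau` | transverse/longitudinal active ratio | 0.23 |
| `k_smc_radial` | radial active stiffness | 0.01 |

Geometric distribution parameters (radians for angles, strain for
recruitment) default to the packaged statistical averages
(`statistical_default_config()`): adventitial elastin families at
(0.25, 1.84) with SDs (0.17, 0.38), collagen at (0.32, 1.81) with SDs
(0.23, 0.33), medial fiber family (0.23, 0.19), SMC family (0.24, 0.21), a
beta straightening strain calibrated by moment matching to mean 0.35 and SD
0.051 on $[0,1]$, and a uniform medial straightening strain on $[0, 0.35]$.

Several quantities the model needs are not published alongside the
distribution measurements and are therefore packaged as explicit,
configurable assumptions rather than data: the adventitial mixture weights
(equal, $\omega = 0.5/0.5$, since the two measured modes are comparable),
the media/adventitia thickness split (2/3), the layer volume fractions
(SMC-dominant media `IL/E/C/SMC = 0.15/0.25/0.20/0.40`; collagen-dominated,
SMC-free adventitia `0/0.30/0.70/0`), and the beta bounds $[0, 1]$. The
published refined beta shapes (roughly $\alpha_1 \approx 6$,
$\alpha_2 \approx 60$) are mutually inconsistent with the stated moments on
any printed support, so the package calibrates shapes from the moments and
exposes all four beta parameters instead of guessing.

Units are declared once: lengths mm, stresses MPa, forces mN, pressures
mmHg at the interface with 1 mmHg = 1.333224e-4 MPa internally.

## Numerical design

**Orientation and recruitment integrals.** Expectations over the
truncated-normal and beta distributions are computed with density-weighted,
mass-allocated composite Gauss–Legendre rules on each distribution's
effective support (mean ± 10–14 SD, clipped to the nominal support, panels
at ±1, 2, 4 SD, weights renormalised to the exact window mass). The
integration window shrinks with the dispersion, so a fixed node budget
resolves arbitrarily narrow distributions, and the rule collapses *exactly*
to the point-mass mean-value model as SD → 0 — which is what makes the
degenerate-limit equivalence between the full and mean-value models hold to
numerical precision rather than approximately.

**Kinked integrands.** Two integrands are not smooth and would defeat plain
Gauss–Legendre quadrature. (1) The IL elastin strain changes sign inside
its angular range whenever $E_{\theta\theta}$ and $E_{rr}$ have opposite
signs; its plane integrals are evaluated in closed form over the tensile
sub-interval. (2) The collagen recruitment average
$\int D(e_0)\,(e-e_0)_+^{M_C}\,de_0$ has a kink at $e_0 = e$; it is
precomputed per model as a smooth function of $e$ — closed form for uniform
and point distributions, a spline tabulated from a fine master rule for the
beta — so the hot path evaluates a smooth curve. Node-doubling changes
stress components by $<10^{-6}$ relative at the default resolution
(64 angular, 32 recruitment, 64 radial nodes per layer).

**Equilibrium integrals** run per layer in the reference domain
(Gauss–Legendre per layer, so the composition jump at the interface is a
quadrature breakpoint). The inverse problem $p_i(r_o) = p$ is solved by
bracket expansion plus `uniroot`, warm-started along pressure sweeps; the
admissible bracket is bounded below by the radius at which the lumen would
close.

**Degenerate inputs.** Zero-SD orientation and point recruitment
distributions are first-class (the mean-value model); zero activation
short-circuits the SMC term; compressed fibers simply carry nothing. The
active law is clamped at zero far from $\lambda_{max}$ (configurable), so a
contracting cell is never assigned active compression; the radial active
law is gated by the activation level so fully passive SMCs contribute
nothing.

## Parameter estimation

The objective is the mean over the $n \times m$ (pressure × stretch) grid
of the four squared studentised residuals — outer radius and axial force,
passive and K⁺-activated — so both arms inform all parameters jointly;
fitting passive-then-active alone would leave the passive parameters
unvalidated in the low-stretch range where vasoconstriction matters most.
Noise scales default to the generator's true (or floored) per-channel SDs;
for user data they must be supplied.

The optimiser exploits a structural property of the model: passive-state
predictions are completely independent of the active parameters, so
minimising the joint objective by a passive-then-active cascade is
near-exact coordinate descent. Each stage runs a seeded differential
evolution (rand/1/bin, F = 0.8, CR = 0.9, Latin-hypercube initialisation)
in its own subspace — passive material (and fiber-geometry) parameters
against the passive channels, then active (and SMC-geometry) parameters
against the activated channels — each followed by bounded quasi-Newton
refinements (`nlminb`) from the best population members, and a final joint
polish over all parameters. A single joint population search converges far
too slowly in this landscape, which has genuine local minima from
collagen-stiffness/exponent/recruitment and skewness/ratio trade-offs; the
collagen coefficient `k_C` is additionally searched on a log scale because
it spans two decades across vessels. The default budget (population up to
24, 40 generations per stage) completes a full 36-record joint fit in
about ten minutes at the reduced fitting quadrature (12 angular, 8
recruitment, 4 radial nodes — forward-model error well below the fit
tolerances). The seed fixes the entire trajectory: identical seeds give
bit-identical fits.

Three modes mirror three modelling strategies: `statistical_fixed`
estimates material parameters with the packaged microstructure held fixed;
`refined_geometry` additionally estimates the 15 geometric parameters
inside boxes centred on their statistical values (half-width two
across-sample SDs by default — the originally measured SDs are in prior
work and not packaged — configurable via `constraint_sd_mult`); and
`mean_value` collapses all distributions to point masses and estimates mean
angles plus the two straightening strains. Seeding a refined run with the
fixed-mode optimum (`init =`) guarantees the nested-model inequality on the
found optima.

## What the synthetic data does and does not emulate

`generate_experiment()` reproduces the biaxial testing schedule — pressure
0→160 mmHg in 20 mmHg steps, axial stretches 1.3 and 1.5, passive and
fully K⁺-activated states, 36 records — with additive zero-mean Gaussian
noise per channel (default SD 2% of each channel's per-state range, a
declared assumption since rig SDs are not published). It does **not**
emulate preconditioning hysteresis, temperature equilibration, partial
activation dynamics, wall viscoelasticity, or between-vessel microstructure
variability (geometry jitter is off by default). Passing the recovery tests
therefore demonstrates identifiability and correctness of the
forward/inverse machinery under the model's own assumptions, not robustness
to real-world model misspecification.

Reference geometries are sampled at porcine LAD scale (outer radius 2–3 mm,
wall/outer ratio 0.2–0.35, opening angle 0.5–2.5 rad); the published study
does not print its specimens' zero-stress geometries, so these are labelled
synthetic ranges.

## Problem sizes used by the test-suite and acceptance script

Closed-form targets (active-law peak, stress ratio, beta calibration,
fixture averages) run at full precision. Mechanics invariants use a
16/8/6-node quadrature model whose error is far below the asserted
tolerances. The parameter-recovery exercise fits all ten material
parameters to the noiseless 36-record protocol with the default optimiser
budget; the noisy-replicate bias check uses a reduced three-parameter,
single-stretch design with ten replicates. These sizes are the package's
own choices for a self-contained, deterministic validation suite.

## Known limitations

* The active model is phenomenological; only $\lambda_{max}$ and
  $\sigma_{max}$ are directly physical, and the axial response is tied to
  the circumferential one through the single ratio $\tau$.
* Volume fractions and the layer split are assumptions, not measurements;
  absolute transmural stress magnitudes shift with them (directional
  behaviour does not).
* The conjugacy of the scalar active stress in the chain-rule assembly is
  taken exactly as written (the scalar multiplying $\partial\lambda/
  \partial\mathbf{E}$); no pull-back correction is applied.
* Single-angle (planar) dispersion only; no two-angle 3D orientation
  spread, no fiber–fiber interaction, no damage or viscoelasticity, no
  perivascular constraint or fluid–structure interaction.
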