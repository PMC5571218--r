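# coromicro

Microstructure-based passive and active mechanics of coronary arteries.

`coromicro` implements a three-dimensional structural constitutive model of
the coronary artery wall for researchers in vascular biomechanics. Rather
than fitting a phenomenological strain-energy function, the wall stress is
assembled from its measured microstructure: orientation-distributed elastin
and collagen fibers in the adventitia and media, an isotropic inter-lamellar
elastin network, beta/uniform-distributed collagen straightening
(recruitment) strains, and smooth muscle cells (SMCs) with an asymmetric
triaxial active contraction law. The loaded vessel is treated as an
incompressible, residually stressed thick-walled tube, so the package can
predict pressure–radius and pressure–axial-force curves, transmural Cauchy
stress profiles, and the micro-stresses on individual constituents — and
invert the problem to estimate material parameters from biaxial
(distension–extension) test data.

## The model

**Kinematics.** The stress-free reference state is the radially cut-open
sector (opening angle Θ). Incompressibility maps reference radius *R* to
loaded radius *r*:

    r(R) = sqrt( r_o² − (R_o² − R²)·(π − Θ)/(λ_z π) ),

with stretches λ_θ = (π/(π−Θ))·r/R, λ_r = ∂r/∂R, λ_θ λ_r λ_z = 1, and
Green–Lagrange strain E = (FᵀF − I)/2.

**Passive stress.** Each fiber family contributes a volume-weighted
orientation integral of its single-fiber law,
S = Σᵢ fᵢ ∫ ℛᵢ(θ) (∂wᵢ/∂e) N⊗N dθ, with affine fiber strain
e = E : N⊗N. Elastin is linear and tension-only (w = k_E e²/2); collagen is
a tension-only power law k_C (e − e₀)^{M_C} engaged beyond its straightening
strain e₀, averaged over the recruitment distribution. Adventitial fiber
orientations follow bimodal truncated-normal mixtures; medial fibers and
SMCs follow mirrored families about the circumferential axis; inter-lamellar
elastin is isotropic in the circumferential–radial plane.

**Active stress.** Along the cell axis,
σ = A·[ρ₁/2·(λ_max^{ρ₂} − λ^{ρ₂} − 2)(λ − λ_max)² + σ_max], peaking at
σ_max when λ = λ_max; the transverse response is the same law scaled by τ;
the radial response is linear (k_SMC). The second Piola–Kirchhoff
contribution follows the chain rule σ·∂λ/∂E summed over the three cell axes
and averaged over the SMC orientation family.

**Equilibrium.** Radial equilibrium of the closed tube gives the luminal
pressure p_i = ∫(σ_θθ − σ_rr)/r dr, the reduced axial force
F = π∫(2σ_zz − σ_θθ − σ_rr) r dr, the axial tension N = F + p_i π r_i², and
the transmural stress profile with σ_rr(r_o) = 0.

**Estimation.** Passive and active parameters are fitted jointly by
minimising the mean squared studentised residual of outer radius and axial
force in both the passive and the K⁺-activated state, using seeded
differential evolution with a bounded local polish. Microstructural
distribution parameters can be held at their packaged statistical values,
refined inside boxes centred on them, or collapsed to a single-angle
"mean-value" model.

## Worked example

```r
library(coromicro)

model <- artery_model(reference_geometry(R_outer = 2.5, R_inner = 1.75,
                                         opening_angle = 1.4),
                      quadrature = quadrature_spec(16, 8, 6))

sim <- simulate_protocol(model, pressures = c(60, 100), stretches = 1.3)
sim
#> # A tibble: 4 × 7
#>   pressure_mmHg lambda_z state   r_outer_mm r_inner_mm axial_force_mN axial_tension_mN
#>           <dbl>    <dbl> <chr>        <dbl>      <dbl>          <dbl>            <dbl>
#> 1            60      1.3 full          1.45      0.868          30.4              49.4
#> 2           100      1.3 full          1.59      1.08            1.24             50.5
#> 3            60      1.3 passive       1.67      1.20           -9.83             26.5
#> 4           100      1.3 passive       1.76      1.32          -46.9              26.5
```

At 60 mmHg, K⁺ activation contracts the vessel (outer radius 1.45 mm vs
1.67 mm passive) and raises the reduced axial force by ~40 mN — the biaxial
vasoactivity produced by the obliquely arranged SMC families. The axial
tension adds the pressure acting on the closed tube's ends,
`N = F + p_i π r_i²`.

```r
autoplot(sim)                                   # pressure-radius / pressure-force figure
prof <- transmural_profile(model, 1.3, 1.76, "passive")
head(prof, 2)                                   # sigma_rr runs from -p_i to 0

# synthetic biaxial test + joint parameter estimation
data <- generate_experiment(model, seed = 11, noise_frac = 0)
fit  <- fit_parameters(data, model, fit_config(seed = 3))
tidy(fit); glance(fit)
```

A command-line front end over the same functions lives at
`inst/cli/coromicro.R` (subcommands `generate`, `simulate`, `profile`,
`fit`, `recover`).

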