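---
title: "Models and methods in gravicreep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gravicreep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravicreep)
```

# The physical problem

Giant oocyte nuclei (~400 μm across) contain dense, liquid-like RNP bodies
— nucleoli and histone-locus bodies — embedded in an intranuclear actin
mesh. The bodies are denser than the nucleoplasm by some tens of kg/m³, so
each experiences a constant buoyancy-corrected weight
F = (4/3)πR³·Δρ·g. The mesh is not a permanent solid: under any sustained
force it flows. The package quantifies three linked things: (i) the
viscoelasticity of the mesh from forced-bead microrheology, (ii) the
spatial statistics of nuclear bodies as they slowly settle, and (iii) a
particle-level simulation of settling and coalescence.

# The viscoelastic model

The material model used everywhere is the **extended Kelvin–Voigt
element**: a spring E (Pa) in parallel with a dashpot η₂ (Pa·s) — the
Kelvin–Voigt body, which sets a retarded elastic response with time
constant τ = η₂/E — in series with a dashpot η₁ (Pa·s) representing
long-time network flow. Its creep compliance is

$$J(t) = \frac{1}{E}\left(1 - e^{-tE/\eta_2}\right) + \frac{t}{\eta_1}.$$

At short times the element looks elastic with plateau 1/E; at long times
it flows with viscosity η₁. The frequency-domain description follows from
the complex compliance $J^*(\omega) = 1/(E + i\omega\eta_2) +
1/(i\omega\eta_1)$ and $G^*(\omega) = 1/J^*(\omega)$, giving

$$G'(\omega) = \frac{E\,\omega^2\eta_1^2}{E^2 + \omega^2(\eta_1+\eta_2)^2},
\qquad
G''(\omega) = \frac{\omega\eta_1 E^2 +
\omega^3\eta_1\eta_2(\eta_1+\eta_2)}{E^2 + \omega^2(\eta_1+\eta_2)^2}.$$

These closed forms are derived from the stated model structure and are
validated in the test suite against two independent oracles: complex
arithmetic inversion of $J^*(\omega)$, and a numerical Fourier
transformation of time-domain $J(t)$ samples (the terminal slope is split
off analytically so the transform integrand decays). Agreement is within
1% over ω ∈ [0.1, 3] rad/s for both reference parameter sets, which is
the model-level statement that creep and oscillatory measurements must
describe the same material.

Two reference parameter sets recur in the tests: the creep-route set
(E = 0.14 Pa, η₂ = 0.15 Pa·s, η₁ = 1.7 Pa·s) and the oscillatory-route set
(E = 0.10 Pa, η₂ = 0.05 Pa·s, η₁ = 0.9 Pa·s).

# Units

Internal units are μm, s, pN and Pa. The identity 1 Pa = 1 pN/μm² makes
Stokes expressions come out without conversion factors: ζ = 6πηR is
directly pN·s/μm. Densities stay in kg/m³ and effective gravity is a
dimensionless multiple of g₀ = 9.81 m/s²; a single 10⁻⁶ factor converts
the μm³·kg/m³·m/s² product into pN. Thermal energy is
kB·T = 1.38 × 10⁻⁵·T pN·μm (≈ 4.11 × 10⁻³ at the default 298 K). This
convention keeps every quantity near unity and avoids float underflow.

# Microrheology estimation

**Sinusoid fitting.** At known drive frequency, fitting is linear least
squares in the (sin ωt, cos ωt, 1, t) basis — exact, convex, and with a
closed-form answer, so no iterative-fit failure modes. The phase lag is
δ = φ_F − φ_x wrapped to [0, π): δ = 0 is purely elastic, π/2 purely
viscous. A linear drift term is included by default because magnetic-bead
recordings commonly drift; it is toggleable.

**Simultaneous moduli fitting.** G′ and G″ are fitted jointly over
(E, η₂, η₁) on the log scale (positivity by construction), minimizing the
weighted sum of squared residuals: inverse-variance weights when per-point
uncertainties are supplied, otherwise inverse-magnitude weights (uniform
relative weighting). Initialization is data-driven — E from the G′
plateau, η₁ from the terminal G″/ω, η₂ from the high-frequency G″/ω with
the series correction removed — plus random restarts; Nelder–Mead then
BFGS polish. Parameter 95% intervals use a seeded parametric bootstrap
(200 replicates by default). The bootstrap is a stand-in choice: the
original analysis reports 95% CIs without stating a method.

**Creep fitting.** Least squares of the J(t) form with a neutral
data-driven start (terminal slope → η₁, tail intercept → 1/E). Two flags
guard interpretation: `short_window` when the record is shorter than ~3
retardation times (η₁ poorly separated from η₂), and `degenerate` when
the fitted elastic plateau is below curve resolution (a pure fluid —
E is then unbounded above and meaningless).

**Lissajous analysis.** The force–displacement loop of a linear
viscoelastic material is an ellipse enclosing the dissipated energy per
cycle, πF₀x₀ sin δ. Fitting uses the direct least-squares ellipse method
(Fitzgibbon) on standardized coordinates; collinear loops (δ = 0) return
a degenerate line descriptor with zero area rather than an error.

**Bead radius.** The probe beads are nominally 2.8 μm diameter, so
`BEAD_RADIUS_PRESETS["nominal"]` = 1.4 μm is the default; an
imaging-based 1.5 μm estimate is kept as the `"imaging"` preset.

# Spatial statistics

The pipeline mirrors how a segmented image stack is reduced: per-plane
(z, center, area) → axis-aligned ellipsoid (the cross-section area of an
ellipsoid is quadratic in z, so this is a linear fit) → linear map onto a
sphere of radius equal to the geometric mean of the semi-axes
(volume-preserving; distances are not inflated) → rotation (det +1)
carrying the centroid-to-mean-body direction onto −z, with z = 0 at the
nucleus bottom. From per-plane areas alone the two horizontal semi-axes
are only identified as a product; when the segmentation also yields
per-plane x/y half-extents they are resolved separately.

z₀ is reported as an absolute distance (that is how it is defined); the
signed offset is retained for displacement arithmetic. Δz is reference
mean height minus cohort mean height, positive downward. The creep
velocity regression is forced through the origin because Δz is defined as
zero at t = 0. The force–time collapse rescales each condition's time
axis into u = (2/9)Δρ·g₀·g·R²_med·t and pools a single
through-the-origin regression; the *median* body radius drives the
scaling (the size distribution is heavy-tailed, so the mean is dominated
by rare large bodies). Δρ is a required parameter defaulting to 50 kg/m³
— a plausible nucleolus–nucleoplasm contrast, not a value printed with
this analysis — and every derived timescale scales as 1/Δρ.

Size distributions are fitted as a **truncated continuous power law** by
maximum likelihood with a profile-likelihood CI, not by log-binned least
squares (binned LS on heavy tails is biased; the MLE is checked against a
brute-force likelihood grid). The log-binned histogram is still returned
for display. Correlations use Fisher's z: the 95% CI is
tanh(atanh r ± 1.96/√(n−3)).

# The simulator

Bodies are disks for collision geometry in a 2D (x, z) box but carry 3D
volumes for weight and drag (R = (3V/4π)^{1/3}) — the only consistent
reading of 2D dynamics with volumetric fusion and Stokes drag. Per step:
deterministic drift −(VΔρg/ζ)Δt in z, Gaussian kicks of variance
2(kBT/ζ)Δt per axis, reflection of centers at the wall-clearance planes
[R, L−R], then fusion: every overlapping pair merges (ascending
surface-gap order, iterated to a fixpoint) into a body with the summed
volume at the volume-weighted centroid. Total volume is conserved
exactly; particle count never increases. Only the long-time viscosity η₁
enters the drag — the short-time elastic caging of the Kelvin–Voigt body
is deliberately not simulated, matching the long-timescale question the
simulation answers.

The timestep rule requires one step's drift plus three standard
deviations of the Brownian step to stay below a particle diameter,
checked at both volume bounds (drift binds for the largest bodies,
diffusion for the smallest), then halved as a safety factor.

**Box size.** The default box is 400 μm — the nucleus diameter, so the
200-μm disruption threshold (the nucleus radius) fits inside it. At that
crowding, with 1,000 bodies, fusion is frequent enough that the *mean*
height of surviving bodies is shaped not only by drift but by a
survivor-selection effect: large sinking bodies preferentially absorb
small low-lying ones, so the surviving small bodies sit higher. At 1 g
this bias can exceed the (tiny) drift on desk-scale runs and the mean can
transiently rise. At 100–1,000 g drift dominates and Δz(t) is linear
early, crossing thresholds at times scaling as 1/g. The early-time
linearity test therefore runs at the source model's number density
(300 bodies in an 800-μm box ≈ 1,000 in 1,600 μm) and drift-dominated
gravity; the 1/g-scaling test keeps the 400-μm default. Related: the
median body radius is *not* monotone during partial sedimentation (the
median under pairwise merging is not order-preserving, and the survivor
effect can pull it down before floor coalescence pulls it up); the tests
assert count monotonicity, exact volume conservation, long-run median
growth and the positive Δz–median-size coupling instead.

# The synthetic-data generators: the stated world

The generators' defaults encode the experimental conditions, not tuned
values: oscillatory forcing at 0.02–1 Hz and 0.2–1.75 pN on 1.4-μm beads;
step-force records covering at least five retardation times plus a flow
tail; nuclei with semi-axes (220, 200, 180) μm sliced at the 2-μm imaging
step; body volumes power-law with exponent −1.5 between 0.5 and 4,000 μm³
(radii ~0.5–10 μm); centrifugation cohorts at 10/100/1,000 g on the
experimental time grids (20 min–14 h, 10–100 min, 2–20 min respectively).

The cloud generator tilts the vertical density as
p(z) ∝ A(z)·exp(−z/λ), A(z) the ellipsoid cross-section area — a
single-parameter monotone family chosen because no generative form is
prescribed by the source analysis. λ is solved by quadrature so the
*expected* asymmetry measured after sphere normalization equals the
target z₀ (the raw-frame offset is pre-scaled by c/s, s the geometric
mean radius, because normalization rescales z by s/c).

What the generators do **not** emulate: raw pixel data, segmentation and
tracking errors, body–body exclusion in clouds, nucleus-to-nucleus shape
variability, and any short-time elastic caging of sedimenting bodies. A
green recovery test therefore establishes that the estimators invert the
stated generative model at the stated noise — not that they are robust to
every failure mode of real microscopy data.

# Numerical choices

- Log-parameterized optimization for all positive parameters; multiple
  starts; Nelder–Mead then BFGS.
- Gaussian sizing uses `nls` with `scaleOffset` (so noise-free,
  zero-residual profiles converge) and falls back to direct least squares
  via `optim` if the `nls` gradient degenerates.
- Fusion ties are broken by ascending surface gap; merging is iterated to
  a fixpoint so overlap chains collapse deterministically.
- All randomness flows from explicit seeds; identical (config, seed)
  gives bit-identical simulation output.
- Degenerate inputs return flagged results rather than errors where the
  quantity is still defined (collinear Lissajous loops, pure-fluid creep,
  body mean coincident with the centroid).

# Known limitations

- The simulator is 2D with volumetric bookkeeping; no hydrodynamic
  interactions, droplet deformation, Ostwald ripening, or 3D geometry.
- The ellipsoid fit is axis-aligned (vertical stack axis); arbitrarily
  tilted nuclei would need a rotated per-plane model.
- Bootstrap CIs are a methodological stand-in (see above).
- Δρ, temperature and the simulation box side are configuration
  parameters, not measured quantities; timescale predictions inherit
  their uncertainty linearly (τ\* ∝ 1/Δρ).
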