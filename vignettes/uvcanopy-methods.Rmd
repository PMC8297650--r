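---
title: "Modelling UV-B interception and bioactive-compound yields in rosette canopies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling UV-B interception and bioactive-compound yields in rosette canopies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvcanopy)
```

## The problem

Supplemental UV-B in plant factories is a standard tool for raising total
phenolic (TPC) and flavonoid (TFC) concentrations in leafy *Brassica* crops.
The difficulty in interpreting such experiments is that the dose that matters
physiologically is the energy *absorbed by each leaf*, not the energy emitted
by the lamps: in a rosette canopy with spiral phyllotaxis, upper (young)
leaves shade middle and lower (old) ones, and the disparity grows with the
stand's leaf area index. `uvcanopy` provides the full computational chain
needed to quantify this:

1. a synthetic 3D rosette generator (stand-in for 3D scans),
2. a plant-factory scene builder (bed, LED bars, stand density),
3. a Monte Carlo ray tracer tallying absorbed power per leaf,
4. UV dosimetry with biological weighting,
5. regression of compound responses on cumulative absorbed UV, the slope
   of which is the **UV energy yield** — the UV analogue of radiation use
   efficiency.

## The transport model

Each LED bar is a rectangular Lambertian emitter: ray origins are uniform on
the emitting face and directions cosine-weighted about the downward normal.
A ray carries weight $P_\mathrm{total}/N$. At each surface hit one outcome is
sampled (Russian roulette): absorption with probability $\alpha$, diffuse
reflection with probability $\rho$ into the incident hemisphere, diffuse
transmission with probability $\tau = 1-\rho-\alpha$ into the far hemisphere.
Leaves are two-sided; the hit side is the sign of the ray–normal product.
Sampling one outcome per hit keeps the estimator unbiased with bounded work
per ray and makes energy conservation exact by construction: every ray's
weight lands in exactly one bin (a leaf, the bed, or "escaped"), so
emitted = absorbed + escaped holds to floating-point rounding on every run.
Intersections use Möller–Trumbore against a median-split bounding-volume
hierarchy; the BVH affects only speed, never results. The RNG is a
hand-rolled splitmix64-seeded xoshiro256+, so tallies are bit-reproducible
for a fixed seed independent of the C++ standard library.

The per-leaf absorbed-power estimate is $\hat P_s = P_\mathrm{total}\,k_s/N$
with $k_s$ the number of rays absorbed by surface $s$; its Monte Carlo
standard error is the binomial
$P_\mathrm{total}\sqrt{\hat p(1-\hat p)/N}$. The tracer is validated two
ways in the test suite: against a deterministic view-factor oracle
(`analytic_plate_irradiance()`, 4-D Gauss–Legendre quadrature of
$\cos\theta_1\cos\theta_2/\pi d^2$, written and trusted before the engine),
and by the $1/\sqrt{N}$ scaling of the error.

Transport is *band-level* ("grey per band"): one trace per band (PAR
400–700 nm, UV 250–400 nm) with band-integrated source powers and band
optics. Spectral structure inside a band is the business of the dosimetry
module, not transport — the absorptance of a leaf varies slowly enough
within each reporting band that a band-mean value is the conventional
choice in canopy light modelling.

## The synthetic canopy

No scanned kale geometry is distributed with the package, so the generator
produces what the analysis needs: a rosette with leaves at azimuth
$(k-1)\times137.5^\circ$ (spiral phyllotaxis), attachment height rising
linearly with rank (internode parameter), and a triangulated elliptical
blade with a quadratic tip droop (`bend`, default 0.25 of blade length) —
the simplest surface that produces realistic self-shading. Rank 1 is the
oldest leaf; position classes are assigned youngest-to-oldest (upper, then
middle, then lower), matching how leaf positions are scored in practice.

Two presets encode the study conditions:

* **14DAT**: 7 leaves, classes 3/2/2, blade lengths 2.9–5.9 cm, 24 plants
  per 0.40 m² bed (22.2 plants m⁻²) — stand LAI ≈ 0.40;
* **28DAT**: 10 leaves, classes 4/3/3, blade lengths 6.3–14.5 cm, more
  erect leaves (elevation up to 50°), 12 plants per bed (11.1 m⁻²) —
  LAI ≈ 1.60.

Blade dimensions were calibrated once so the stand LAI lands near those two
values; they are not fitted to any simulation output. Per-leaf Gaussian
jitter (azimuth SD 6°, elevation SD 3°, size SD 3%) makes plants
individual; a plant is reproducible from its seed. What the generator does
*not* emulate: leaf twist and curl at high LAI, petiole flexion, venation,
growth over time, or the exact geometry of any scanned cultivar. Canopy
results are therefore structural expectations (orderings, relative gaps),
not predictions of any particular experiment — which is why the tests
assert the upper > middle > lower ordering and the widening of the
positional gap with stage, never specific percentages.

Default optics (replace with measured values where available): leaves
absorb ≈0.87 of PAR and ≈0.94 of UV (UV reflectance 5–6%, transmittance
≈1%, epidermal screening), slightly graded by position class; the bed is
matte white with ρ = 0.5. LED bars default to 4 parallel bars 0.35 m above
the bed, sized so the target bed-plane irradiance times bed area equals
total emitted power (PAR: 200 µmol m⁻² s⁻¹ equivalent; UV: 1.0 W m⁻²).

## Dosimetry

Cumulative dose is exact arithmetic:
$D = E \times h \times 3600 \times d / 1000$ kJ m⁻² for irradiance $E$,
$h$ hours per day and $d$ days. The six-treatment grid
({6, 12} h/day × {1, 2, 3} days) at 1.0 W m⁻² reproduces the dose ladder
21.6, 43.2, 43.2, 86.4, 64.8, 129.6 kJ m⁻². Note the deliberate design
choice: the published dose table for this experimental design is internally
consistent with an effective plant-level irradiance of 1.0 W m⁻², not the
1.2 W m⁻² lamp nameplate, so dose functions take irradiance explicitly and
`effective_irradiance()` derives it from a dose; the package asserts
neither value as "the truth".

Biological weighting uses the generalized plant action spectrum in its
analytic (Green) form,
$\varepsilon(\lambda) = 2.618\,[1-(\lambda/313.3)^2]\,
e^{-(\lambda-300)/31.08}$ below the 313.3 nm cutoff, renormalized to
$\varepsilon(300)=1$. Two routes to an effectiveness factor are provided:
spectral ($\int\varepsilon E\,d\lambda / \int E\,d\lambda$ over a measured
or modelled lamp spectrum) and calibrated (ratio of a printed
biologically-effective dose to its unweighted dose, e.g.
$2.1/21.6 = 0.0972$). They will differ whenever the true lamp spectrum is
unknown — the calibrated route reproduces published dose tables, the
spectral route supports new lamp designs. Photon conversions use exact SI
constants ($E\lambda/hcN_A$); 1 W m⁻² at 310 nm is 2.59 µmol m⁻² s⁻¹, and
against a 200 µmol m⁻² s⁻¹ PAR background that is a 1.3% photon ratio.

## Yield statistics

Per-leaf cumulative absorbed UV over a schedule is
$\Delta UV = \phi \times h \times 3600 \times d / 1000$ kJ m⁻² from the
traced flux density $\phi$. Linear yield fits (`fit_linear_yield`) are
ordinary least squares of concentration on $\Delta UV$ per position class
and stage; the slope is the UV energy yield. The increase-rate model is a
rectangular hyperbola; because the typeset form "a/ΔUV+b" admits three
parses, all three are implemented —
F1: $a/(x+b)$, F2: $ax/(x+b)$, F3: $a/x+b$ — with the saturating F2 as the
default (it is the standard rectangular hyperbola and matches
dose-dependent, saturating increases). The form used is always recorded in
the fit object. Fitting is Levenberg–Marquardt (via `minpack.lm`) with five
multiplicative multi-starts; ties are broken by lowest residual sum of
squares, then lowest $|b|$; non-convergence is reported in a `converged`
flag, never silently swallowed. F3 requires strictly positive doses (it
diverges at zero), which the fitter enforces.

The synthetic assay generator closes the loop for testing: concentration =
class-matched control × (1 + f(ΔUV)/100) + truncated Gaussian noise, with
control rows at ΔUV = 0. Zero-noise data round-trips through the fitters to
machine precision; at 5% multiplicative noise and n = 60, generating
parameters are recovered within 10% (median over seeds) — both properties
are asserted in the tests.

## Numerical choices and degenerate inputs

* Intersection epsilon $10^{-7}$ m with the just-hit triangle excluded,
  preventing self-intersection on shared fan edges at metre scale.
* `max_bounces` default 10; deeper paths carry < 0.1% of power at leaf
  absorptances ≥ 0.87 and are tallied as escaped (never dropped), so the
  balance stays exact.
* Band integration is trapezoidal on the native wavelength grid with
  linear interpolation at band edges; no-overlap bands return 0 with a
  warning rather than an error.
* Degenerate triangles are rejected at trace time; degenerate regression
  designs (all-equal doses, n < 3) are rejected with informative errors.
* Schedules with 0 days yield zero dose (not an error).
* The empty scene (bed only) is valid and used by conservation tests.

## Problem sizes

Default tests and examples use 10⁴–10⁶ rays; a 24-plant canopy trace at
2×10⁵ rays takes well under a second on one core (the engine is compiled),
and the full test suite runs in tens of seconds. These sizes give
Monte Carlo errors of ≈1% on per-class means, which is an order of
magnitude below the positional effects being measured (30–120% gaps).

## Known limitations

* The rosette is parametric, not scanned; absolute flux magnitudes and
  exact positional percentages are preset-specific.
* Diffuse (cosine) leaf scattering only — no specular component, no
  refractive transmission, no polarization.
* Band-level transport assumes optics constant within a band.
* The action spectrum's analytic form is one published formulation;
  `be_factor()` accepts any replacement weighting function.
* Assay noise is additive Gaussian truncated at zero; real assay error is
  likely heteroscedastic.
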