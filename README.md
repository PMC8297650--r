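# uvcanopy

Monte Carlo modelling of PAR and UV-B radiation interception in 3D rosette
canopies under LED arrays, with UV dosimetry and dose–response "UV energy
yield" regression.

## What it is for

Supplemental UV-B raises total phenolic (TPC) and flavonoid (TFC)
concentrations in leafy crops grown in plant factories, but the effective
stimulus is the UV energy *absorbed by each leaf*, which varies strongly
with leaf position and growth stage: in a spiral-phyllotaxis rosette, young
upper leaves shade older ones, and the disparity grows with leaf area
index. `uvcanopy` is for researchers in controlled-environment agriculture
and plant photobiology who need to turn lamp settings into per-leaf
absorbed doses and relate compound responses to those doses.

The package provides, end to end:

* **Synthetic 3D rosettes** — spiral phyllotaxis (137.5° divergence),
  triangulated drooping elliptical blades, growth-stage presets
  (`14DAT`: 7 leaves, stand LAI ≈ 0.40; `28DAT`: 10 leaves, LAI ≈ 1.60);
* **Scene builder** — growth bed, rectangular Lambertian LED bars, plants
  placed at the stand density, per-band leaf/bed optics; ASCII OBJ/PLY
  mesh and JSON scene round trips;
* **Monte Carlo ray tracer** (compiled, BVH-accelerated) — per-leaf
  absorbed power per band with binomial Monte Carlo standard errors and an
  exact energy balance (emitted = absorbed + escaped by construction);
  validated against a deterministic view-factor quadrature oracle;
* **Dosimetry** — cumulative doses `E·h·3600·d/1000` kJ m⁻², biologically
  effective weighting with the generalized plant action spectrum
  (ε(λ) = 2.618[1−(λ/313.3)²]e^(−(λ−300)/31.08), normalized to ε(300)=1),
  photon conversions with exact SI constants, the six-treatment exposure
  grid ({6,12} h/day × {1,2,3} days);
* **Response models** — RSA = (A_ctrl − A_sample)/A_ctrl × 100,
  Fv/Fm = (Fm − F0)/Fm, OLS yield fits (slope = UV energy yield,
  concentration units per kJ m⁻²), and the rectangular-hyperbola
  increase-rate model in all three parses of `a/ΔUV+b`
  (default the saturating `a·ΔUV/(ΔUV+b)`);
* **Pipeline** — `run_pipeline()` drives generate → trace → dose → assay →
  fit from one config with a single seed, reproducing byte-identical
  outputs.

## Worked example

```r
library(uvcanopy)

scene <- canopy_scene("28DAT", seed = 1)   # 12 plants on a 0.8 x 0.5 m bed
leaf_area_index(scene)
#> 1.66

r <- trace(scene, "UV", trace_config(n_rays = 2e5, seed = 1))
s <- summarize_by_position(r)
s$by_class
#>   position_class mean_flux_W_m2 se_flux_W_m2  n
#> 1          upper          0.388       0.0142 48
#> 2         middle          0.321       0.0178 36
#> 3          lower          0.180       0.0118 36
round(s$percent_above, 1)
#> middle  lower
#>   20.6  115.8
```

Upper leaves absorb on average 0.39 W m⁻² of UV — 21% more than middle and
116% more than lower leaves — although every plant sits under the same
bars: the gap is pure canopy structure (self- and neighbour shading plus
distance from the bars). The flatter 14DAT stand shows a much smaller gap,
which is the central structural effect the package quantifies.

Cumulative absorbed UV per leaf over the strongest treatment, and the dose
bookkeeping behind it:

```r
uv <- cumulative_absorbed_uv(r, exposure_schedule(12, 3))
head(uv, 3)
#>   plant_id leaf_id position_class treatment cumulative_absorbed_uv
#> 1        1       1          lower  3 d 12 h                   21.3
#> 2        1       2          lower  3 d 12 h                   12.4
#> 3        1       3          lower  3 d 12 h                   17.5

bef <- calibrate_be_factor(21.6, 2.1)      # effectiveness factor 0.0972
dose_summary(1.0, treatment_grid()[["3 d 12 h"]], bef)
#> $label            "3 d 12 h"
#> $unweighted_kJ_m2 129.6
#> $be_kJ_m2         12.6
#> $be_factor        0.0972
```

So the `3 d 12 h` schedule at 1.0 W m⁻² delivers 129.6 kJ m⁻² unweighted,
equivalent to a biologically effective dose of 12.6 kJ m⁻² — while
individual leaves absorb anywhere from ~12 to ~28 kJ m⁻² depending on
position. Feeding those per-leaf doses through `generate_assay_data()` and
`fit_linear_yield()` / `fit_hyperbolic()` yields per-position UV energy
yields and their R²; `run_pipeline(smoke_config(), "out")` runs the whole
chain and writes every table.

See `vignettes/uvcanopy-methods.Rmd` for the transport model, the
calibration of the presets, all defaults and their rationale, and known
limitations.

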