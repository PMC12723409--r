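# axonsf

Structure–function analysis of myelinated white-matter pathways: how the
diameters of axons, measured structurally, relate to the conduction times a
pathway actually achieves.

The package is written for researchers who combine some or all of:

* **strong-gradient diffusion MRI** of fixed brain tissue, fitted with the
  powder-average (spherical-mean) cylinder model to estimate an axon
  diameter index per voxel;
* **transmission electron microscopy** of the same tract, segmented into
  axon/myelin label masks, from which per-axon inner diameter, myelin
  thickness and g-ratio are measured;
* **evoked local field potentials**, whose first positive deflection (P1)
  times the conduction across the pathway.

## The models at the core

**Diffusion.** Restricted diffusion perpendicular to a cylinder of radius
*R* attenuates a PGSE signal according to the Gaussian-phase-distribution
series over Bessel-derivative roots; the apparent perpendicular diffusivity
*D*⊥ = −ln *S*⊥/*b* is gradient-strength independent for shells sharing
(δ, Δ). The powder-averaged signal of the intra-axonal compartment,

&nbsp;&nbsp;S̄(b) = vₐ e^(−b D⊥) √(π / (4b(D∥ − D⊥))) · erf(√(b(D∥ − D⊥))),

is fitted per voxel for (vₐ, D⊥) with the intrinsic diffusivity D₀ fixed,
and D⊥ is inverted to a diameter on the monotone forward map. A Monte-Carlo
sensitivity profile (Rician noise, 0.2–15 µm grid) quantifies the band of
diameters the acquisition can actually resolve.

**Morphometry.** Blob analysis isolates myelinated axons, assigns shared
myelin to the nearest axon, and measures inner/outer diameters from the
minor axes of moment-fitted ellipses. Fibers are rejected for missing
myelin, border overlap, low myelin perimeter coverage, or high
eccentricity, with preparation-specific thresholds (Epon 0.95/0.92,
Cryo 0.85/0.975) and per-reason accounting. Distributions are summarized by
mean, SD, KDE mode, p90 and the tail-weighted MR-effective diameter
d_w = 2(⟨R⁶⟩/⟨R²⟩)^¼.

**Shrinkage.** Dehydrated (Epon) material shrinks relative to cryo-fixed
material, more so in the tail: s = (Cryo − Epon)·100/Cryo on the mode and
p90, averaged into a general factor; correction divides by (1 − s/100).

**Conduction.** CV = L/TCT and CV = (5.5/g)·d combine into the
bidirectional conversions d = L·g/(5.5·TCT) and TCT = L·g/(5.5·d).

## Worked example

```r
library(axonsf)

## shrinkage from the two preparations' group summaries (mode / p90 in um)
shrinkage_factor(list(mode = 0.31, p90 = 0.66),
                 list(mode = 0.39, p90 = 1.42))
#> shrinkage: mode 20.5%, p90 53.5%, general 37.0%

## rat pathway: 5.57 ms conduction over 11.47 mm at g = 0.64
predict_diameter(TCT = 5.57, L = 11.47, g = 0.64)
#> [1] 0.2396213

## human pathways: 5-13 ms over 111.4-122.4 mm at g = 0.7
human_extrapolation(c(5, 13), c(111.4, 122.4), g = 0.7)
#>      min      max
#> 1.090629 3.115636

## synthetic TEM mask with injected rule violations, analysed end to end
gm <- gen_tem_mask(40, target = "epon", width = 1600, height = 1600,
                   pixel_size = 0.01,
                   violations = c(border = 2, unmyelinated = 2, high_ecc = 2),
                   seed = 7)
res <- analyze_mask(gm$mask)
res$counts
#>            accepted           no_myelin            min_area              border
#>                  40                   2                   0                   2
#>        low_coverage   high_eccentricity myelin_without_axon
#>                   0                   2                   0
res$stats
#> n = 40: mean 0.474, sd 0.219, mode 0.383, p90 0.794, d_w 0.757
```

The shrinkage output says the dehydrated preparation understates the
distribution mode by ~21% and its 90th percentile by ~53% relative to
cryo-fixation — larger axons shrink more — giving a general correction
factor of 37%. The conduction-time conversion places the axons carrying the
rat's measured latency at ~0.24 µm, below the mode of the EM distribution,
while human conduction times imply 1.09–3.12 µm. In the morphometry run,
all 40 clean synthetic axons are accepted and each injected violation is
excluded for exactly the intended reason.

Other entry points: `run_sensitivity()` / `summarize_bounds()` for the
acquisition's diameter sensitivity band, `fit_diameter_map()` for voxel-wise
dMRI fitting, `detect_peaks()` / `reliability_cov()` for evoked-potential
latencies, and `run_report()` to assemble every available modality into one
structure–function report. The methods vignette
(`vignettes/axon-structure-function.Rmd`) documents the models, defaults
and design decisions.

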