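---
title: "Methods: from axonal microstructure to conduction time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from axonal microstructure to conduction time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonsf)
```

`axonsf` connects three ways of looking at the same white-matter pathway: the
diameters of its axons measured under the electron microscope, the diameter
index a strong-gradient diffusion MRI acquisition reports for the same
tissue, and the conduction time an evoked potential measures functionally.
This vignette explains the models behind each stage, the parameters that
matter, and the design decisions taken where the methods literature leaves
the details open.

## The diffusion model

Water restricted inside an axon of radius $R$ attenuates a pulsed-gradient
spin-echo (PGSE) signal applied perpendicular to the fiber according to the
Gaussian phase distribution (GPD) approximation. For rectangular pulses of
strength $G$, duration $\delta$ and separation $\Delta$ the log-attenuation
is a series over the roots $\beta_m$ of $J_1'$, the derivative of the
first-order Bessel function (`gpd_perpendicular_signal()`). Two properties
anchor the implementation:

* In the wide-pulse regime the log-attenuation scales as $R^4$, which is why
  small axons vanish from the measurement long before large ones.
* Both the GPD log-attenuation and the b-value scale with $G^2$, so the
  apparent perpendicular diffusivity $D_\perp = -\ln S_\perp / b$ is exactly
  the same for all shells that share $(\delta, \Delta)$. This is what makes
  a single $D_\perp$ across the three shells a valid parameterization,
  realized in `effective_Dperp()`.

Orientation is factored out by powder averaging: the arithmetic mean of the
signal over uniformly distributed gradient directions. For an axially
symmetric compartment with diffusivities $(D_\parallel, D_\perp)$ it has the
closed form
$$\bar S(b) = v_a\, e^{-b D_\perp} \sqrt{\frac{\pi}{4 b (D_\parallel - D_\perp)}}\,
\mathrm{erf}\!\left(\sqrt{b (D_\parallel - D_\perp)}\right),$$
with $v_a$ the intra-axonal signal fraction (`smt_powder_signal()`). At the
b-values of the diameter protocol (17,560-24,450 s/mm²) extra-axonal water
is assumed fully attenuated, so the model contains a single compartment; no
dot compartment or orientation dispersion model is attempted.

Estimation (`fit_smt()`) is bounded non-linear least squares over
$v_a \in [0,1]$ and $D_\perp \in [0, D_0]$ with $D_0$ held fixed, best of
five starts on a $(v_a, D_\perp)$ grid, because the objective has a shallow
valley at low $D_\perp$. The fitted $D_\perp$ is inverted to a cylinder
diameter by bisection on the monotone forward map
(`diameter_from_Dperp()`); estimates below 0.1 µm are discarded from
distribution summaries and voxels whose $D_\perp$ sits at the lower bound
are reported as a separate "zero" state, both counted rather than silently
dropped.

### Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| $\gamma$ | 2.6752218744e8 | rad s⁻¹ T⁻¹ | proton; confirmed by the printed b-values at 0.1% |
| $\delta$, $\Delta$ | 8, 18 | ms | diameter protocol timings |
| $D_0$ | 0.6 | µm²/ms | typical fixed-tissue, room-temperature intra-axonal axial diffusivity for post-mortem scanning; configurable |
| b0 threshold | 50 | s/mm² | absorbs header rounding when flagging unweighted images |
| discard limit | 0.1 | µm | sub-resolution diameter estimates |
| SNR | 50 | — | magnitude-image signal-to-noise of the acquisition |

The inverted diameter depends on $D_0$ only as $d \propto D_0^{1/4}$
(doubling $D_0$ moves mid-band diameters by a factor 1.14-1.19 in the
implementation's own tests), so moderate uncertainty in $D_0$ is benign for
single diameters. The *sensitivity band* inherits the same quarter-power
scaling, which is worth keeping in mind when comparing bands across studies:
a $D_0$ estimated by a diffusion-tensor fit at b = 4000 s/mm² is biased low
by the non-Gaussianity of the signal at that b, and a lower $D_0$ shifts the
whole band toward smaller diameters. We keep a literature-motivated fixed
0.6 µm²/ms rather than emulating that bias.

## Sensitivity profile

`run_sensitivity()` repeats, for every ground-truth diameter on a
0.2-15.0 µm grid (0.2 µm steps, 50 repeats): generate the 30 directional
signals per shell plus b0 images for a single cylinder, corrupt every
measurement with Rician noise (magnitude of complex Gaussian noise with
real/imaginary SD $1/\mathrm{SNR}$), powder-average, fit, invert. Noise is
applied to each directional measurement *before* averaging, so the powder
average enjoys the $\sqrt{30}$ benefit the real acquisition has; a
`noise_mode = "powder"` alternative applies one noise draw per shell
instead. The fit estimates $v_a$ freely, exactly as the data pipeline does;
`fix_va = TRUE` is available to show the idealized known-$v_a$ precision.

`summarize_bounds()` operationalizes the "reliable band" as the longest
contiguous run of grid diameters whose median relative error stays within a
threshold (default 25%, always reported with the result). At the default
conditions (SNR 50, $D_0 = 0.6$, seed 88) the band comes out
[2.8, 6.6] µm: below it estimates collapse to zero or under half the truth,
above it they saturate and eventually collapse as the signal falls below
the Rician floor. Two systematic effects shape the low end: the noise floor
inflates high-b powder averages, and because $v_a$ is bounded at 1 the fit
can only respond by lowering $D_\perp$, a one-sided bias of order 10% in
diameter near the band edge.

## Electron-microscopy morphometry

`extract_axon_instances()` performs blob analysis on an axon/myelin label
mask: 8-connected axon components, hole filling inside each component, and
assignment of every myelin pixel to its geodesically nearest axon component
(a seeded watershed-style propagation), which separates the shared myelin of
adjacent fibers. Measurements (`measure_axon()`) fit inner and outer
ellipses by second-order image moments; the **minor axis** of each ellipse,
scaled by the pixel size, gives the inner and outer diameters. The minor
axis, not the equivalent-area diameter, is used deliberately: an obliquely
sectioned cylinder elongates its major axis while the minor axis stays near
the true diameter. The g-ratio is the inner/outer diameter ratio and myelin
thickness half their difference.

Filtering (`filter_axon_instances()`) applies, in order: no assigned myelin;
blob below 10 px (a moment ellipse is meaningless below that, a rule added
here and counted as its own reason); overlap of the fiber (axon or sheath)
with the 4-pixel image border; myelin covering less than 95% (dehydrated
Epon material) or 85% (cryo-fixed material) of the axon's boundary pixels;
eccentricity of the inner blob above 0.92 / 0.975 respectively. Coverage is
the fraction of axon boundary pixels with a myelin pixel among their
8-neighbours — the simplest faithful reading of "myelin surrounds the
perimeter" — and eccentricity uses the regionprops convention
$\sqrt{1-(b/a)^2}$ on the inner blob. Exclusions are tallied per reason so
that accepted plus excluded always equals the candidate count.

Distribution summaries (`distribution_stats()`) report mean, sample SD, the
mode of a Gaussian-kernel KDE (Silverman bandwidth, 512-point grid floored
at zero) and the 90th percentile (linear-interpolation quantile). The KDE
mode of a Silverman-bandwidth estimate carries a smoothing bias of a few
percent of scale on skewed laws; the tests assert it within 10% on a gamma
sample rather than pretending it is exact.

## Shrinkage and the tail-weighted diameter

Conventional dehydration shrinks axons relative to cryo-fixation, and
larger axons shrink more. `shrinkage_factor()` evaluates
$s_x = (\mathrm{cryo}_x - \mathrm{epon}_x) \cdot 100 / \mathrm{cryo}_x$ on
the mode and p90 and averages the two into a general factor;
`apply_shrinkage_correction()` divides by $1 - s/100$, the exact inverse of
that definition (a multiplicative variant is available behind a flag).

Because diffusion MRI's voxel-wise estimate is volume-weighted toward large
axons, TEM distributions are also summarized by
$d_w = 2\,(\langle R^6\rangle / \langle R^2\rangle)^{1/4}$
(`mr_weighted_diameter()`), valid in the wide-pulse limit. $d_w$ is a
sixth-moment statistic: it is controlled almost entirely by the largest few
percent of axons. A consequence the tests document honestly: two
distributions calibrated to the *same* mode and p90 can differ by tens of
percent in $d_w$, so a single general shrinkage factor that reconciles the
means of the two preparations does not necessarily reconcile their $d_w$.

## Evoked-potential latencies

`average_and_baseline()` averages the stereotrode channels within each
trial, averages trials, and subtracts the mean of a baseline window
(default −50 to 0 ms; the window is a package choice, not a published
value). `detect_peaks()` takes P1 as the first local maximum with positive
amplitude in (+1, +9) ms and N1 as the global minimum in (+5, +20) ms.
Two robustness controls were added after examining the strict
first-local-maximum rule on noisy averages: a detection floor (default
three times the pre-stimulus SD of the averaged trace) and an optional
dominance window (`peak_window_ms`) requiring a P1 candidate to be the
maximum of its neighbourhood. At a 30 kHz sampling rate, residual averaging
noise superimposed on the rising edge otherwise produces sample-scale local
maxima that fire several milliseconds early — adjacent-sample comparisons on
smoothed, correlated noise are close to coin flips regardless of smoothing.
Defaults keep the strict rule (floor only); `run_report()` uses 0.5 ms
smoothing and a 1 ms window, which recovers injected latencies within
0.1 ms at the generator's default noise. Reliability follows the
coefficient-of-variation rule: per-trial amplitude at the N1 latency, SD
divided by the absolute mean, reliable below 1.00. The N1 onset metric
(first negative crossing after P1) is flagged experimental because no
published definition exists.

## The structure-function conversion

For myelinated CNS axons conduction velocity is approximately linear in
outer diameter, $\mathrm{CV} = 5.5\, d / g$ m/s with $d$ the inner diameter
in µm, and $\mathrm{CV} = L / \mathrm{TCT}$ for a pathway of length $L$.
Combining the two gives the bidirectional conversions
$d = L g / (5.5\,\mathrm{TCT})$ and $\mathrm{TCT} = L g / (5.5\, d)$
(`predict_diameter()`, `predict_tct()`), exact algebraic inverses of one
another. The rat pipeline default is $g = 0.64$ (the TEM cohort mean) with
$L = 11.47$ mm; extrapolation to human pathways uses $g = 0.7$, the
literature optimum. `human_extrapolation()` pairs the longest conduction
time with the shortest pathway (minimum diameter) and vice versa, so the
returned interval covers all combinations; the pairing rule is stated in
the output rather than left implicit.

## What the synthetic data emulate — and what they do not

The generators provide every input the pipeline consumes, with ground
truth:

* `gen_diameter_sample()` draws from a gamma law (lognormal available)
  whose parameters are solved numerically so that the analytic mode and p90
  hit the calibration targets: mode 0.31 / p90 0.66 µm for the Epon-like
  default, 0.39 / 1.42 µm for the Cryo-like one. Mode and p90 pin the body
  of the law, not its extreme tail; any statement about sixth moments rests
  on the gamma assumption.
* `gen_tem_mask()` renders non-overlapping elliptical axons with confocally
  scaled myelin annuli at per-axon g-ratios from a clipped normal
  (0.64 ± 0.04), placing large fibers first and verifying overlap
  pixel-exactly with a 2 px gap. Requested rule violations
  (border-touching, unmyelinated, over-eccentric) are rendered with truth
  flags, their sizes capped at the law's p90 so fixtures always fit. Real
  TEM texture, staining contrast and segmentation errors are *not*
  emulated: a passing morphometry suite demonstrates the rules and the
  geometry, not robustness to imperfect segmentations.
* `gen_dmri_signals()` produces direction-resolved signals of the axially
  symmetric cylinder compartment with Rician noise. With a randomly
  oriented cylinder the 30-point direction set is an imperfect quadrature
  of the spherical mean — a several-percent diameter wobble at mid-band
  that real 30-direction acquisitions share — so precision tests orient the
  cylinder along the direction spiral's pole, where the quadrature is
  nearly exact.
* `gen_lfp()` injects Gaussian-shaped P1/N1 deflections (defaults 5.6 and
  11.8 ms) into two channels with gain mismatch, per-trial offset drift and
  white noise. It does not model line noise, artifacts, or the optogenetic
  channel-kinetics onset delay; latency truth is the injected peak time.

Test problem sizes are deliberately modest — masks up to 2200² px at
0.01 µm/px with a few hundred axons, 50-60 voxel dMRI sets, the full
75 × 50 sensitivity grid — chosen so the entire suite, including the
Monte-Carlo stages, runs in a couple of minutes while leaving every
statistical assertion comfortably powered.

## Numerical choices

* GPD series: first 20 Bessel-derivative roots, located once by bisection
  and cached; adding 5 more roots changes the signal by < 1e-8 at protocol
  parameter ranges (asserted in tests).
* Spherical mean: the erf form switches to a 3-term Taylor series when
  $b(D_\parallel - D_\perp) < 10^{-6}$, keeping the isotropic limit
  continuous.
* Optimizer: `L-BFGS-B` with parameter scaling (0.1 on $v_a$, $0.02 D_0$
  on $D_\perp$) and `factr = 10`; without scaling the shallow valley stalls
  at ~1e-3 relative error, with it noiseless recovery is ~1e-6.
* Inversion: `uniroot` on $R \in [10^{-4}, 10]$ µm, tolerance 1e-9;
  $D_\perp$ above the map's range maps to a capped, flagged 20 µm.
* Ties in peak detection go to the earliest sample; KDE grids are floored
  at zero because diameters are non-negative.
* Degenerate inputs error loudly (empty distributions, all-discarded ROIs,
  rank-deficient tensor designs) rather than returning NaN.

## Known limitations

* The three-shell protocol spans a narrow b range, so $v_a$ and $D_\perp$
  are weakly separable; near the sensitivity band's lower edge this adds a
  one-sided diameter bias under magnitude noise (discussed above).
* $d_w$ comparisons across preparations inherit the generator's tail
  assumption; they are demonstrations of machinery, not claims about real
  tissue tails.
* Masks are consumed, not produced: segmentation quality is upstream of
  this package.
* The conduction model is the linear velocity-diameter relation only;
  internodal length, channel kinetics and temperature are out of scope.
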