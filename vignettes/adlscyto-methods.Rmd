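---
title: "Anti-diffraction light-sheet flow cytometry: models and methods"
author: "adlscyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anti-diffraction light-sheet flow cytometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

adlscyto models a flow cytometer in which the interrogation spot is
replaced by a thin, wide **anti-diffraction light sheet** (ADLS): a row of
Bessel–Gaussian beams written by a spatial light modulator (SLM) and
focused by a modest-NA objective. A particle carried single-file through
the sheet by a hydrodynamically focused jet produces a fluorescence pulse
whose duration encodes its streamwise size. The package implements the
four layers of that instrument — optics, microfluidics, signal formation,
and signal analysis — so the whole chain can be studied, stress-tested
and re-parameterized in software.

## Optical model

The focal field is computed with the Fourier form of the Debye integral:
for a pupil phase $\Phi$ and amplitude $A$, the field at defocus $z$ is

$$E(x, y, z) = \mathcal{F}\left[\, A\, e^{i\Phi}\, p(\theta)\,
E_t(\theta,\varphi)\, e^{i k_z z} / \cos\theta \right],$$

with $k_z = \sqrt{k^2 - k_x^2 - k_y^2}$, $k = 2\pi n_t/\lambda$, and
$\theta = \arcsin(r\,\mathrm{NA}/(R\,n_t))$ the convergence angle at
pupil radius $r$. The transform is implemented unitarily, so pupil and
focal energies agree to rounding error at every $z$ — that identity and
the Fourier shift theorem are the two invariants the test suite checks at
the 1 % level. Two angular-factor modes are provided: the default
aplanatic apodization $p(\theta) = \sqrt{\cos\theta}$ (with the $1/\cos
\theta$ Debye weight), and a plain scalar-Fourier mode with no angular
factors, which is the mode verified against a directly coded discrete
Fourier sum on a 64×64 grid. Polarization is scalar by default; a
Richards–Wolf basis for linearly $x$-polarized input is available
(`polarization = "vector_x"`), since the reference publication does not
state the vectorial field it used.

Phase maps are built from two primitives. The **blazed grating**
$\Phi_1 = 2\pi (f_x \Delta x + f_y \Delta y)$ displaces the focus by
$(\Delta x, \Delta y)$ exactly; it is expressed in the Fourier-conjugate
coordinates of the focal plane because the textbook pupil-coordinate form
omits the focal-length scaling — on the physical pupil this is a ramp of
one cycle per $\lambda R/(\mathrm{NA}\,\Delta x)$. The **axicon**
$\Phi_2 = 2\pi r \tan\alpha/\lambda$ stretches the focus into an extended
Bessel-type segment. The apex-angle parameter $\tan\alpha$ is nowhere
published, so it is a free configuration parameter with a calibration
helper (`calibrate_axicon()`) that root-finds the slope at which the
central-lobe FWHM at the working plane equals a target thickness
(0.8 µm by default); the tuned value (≈ 3.46 × 10⁻³ for the default
pupil) is recorded in the output and used as the shipped default.

Nine beams offset along the sheet axis are multiplexed by **stripe-split
phase** (SSP): pupil rows are assigned cyclically to the beams, each row
carrying its beam's full grating + axicon phase. The exact stripe
geometry of the original method is not reproduced in the reference
publication; horizontal single-sample stripes with cyclic assignment are
used as a documented approximation. Stripe sampling necessarily creates
replica ("ghost") orders along the stripe-stacking axis at the grid field
of view divided by the stripe period; with the default 512² grid these
sit ≈ 8.4 µm from the sheet and are excluded by the region-of-interest
crop in `focal_intensity()`, the same mechanism that excludes the
unmodulated zeroth-order spot. The published beam interval of 8λ is
numerically inconsistent with the published 12 µm sheet width (8 × 8λ ≈
30 µm), so the default spacing is 1.5 µm — nine beams spanning 12 µm —
and the 8λ figure is treated as an alternative preset.

Two numerical choices matter here. First, the pupil is illuminated with a
Gaussian envelope (`gaussian_amplitude()`, waist half the pupil radius by
default): that is the "Gaussian" in Bessel–Gaussian, and it suppresses
the hard-aperture ripple that otherwise modulates the core width along
the focal segment. Second, the working plane is placed deep into the
segment ($z$ = 100 µm by default) where the core width drifts slowly:
with the calibrated slope the central lobe varies by ≈ 11 % over the
range in which an equal-waist Gaussian focus doubles (Rayleigh-range
factor $\sqrt{3}$, ≈ ±5.3 µm) — the quantitative sense in which the
sheet is "anti-diffraction". All sheet metrology (`measure_sheet()`)
reports FWHMs with half-maximum crossings located by linear
interpolation; thickness is the median over (y, z) positions above an
intensity floor, with its standard deviation as the uniformity figure.

## Microfluidic model

The test chamber is a 50 × 10 µm rectangular duct with a 15 µm jet.
Three relations are implemented: the channel Reynolds number
$Re = \rho U_m D_h/\mu$ with $D_h = 2hw/(h+w)$ (2.78 × 10⁻² at
3 µL/h total flow — safely laminar); the jet particle speed
$u_p = k\,Q_{all}/(h w)$ with the empirical correction $k = 0.83$; and
the sizing relation $d_p = u_p \tau - d_s$, where $\tau$ is the pulse
FWHM and $d_s$ the sheet thickness.

A documented inconsistency: the published worked diameters (4.98 µm from
τ = 3.46 ms, 1.09 µm from τ = 1.13 ms) are only consistent with the
*uncorrected* mean channel velocity $U_m = Q_{all}/(hw) \approx$
1.67 mm/s, not with $k U_m$ = 1.38 mm/s nor the measured 1.41 mm/s.
Both velocity models are therefore explicit configuration
(`velocity_model`), and the sizing default is `"mean_channel"`, which
reproduces the worked examples. Widths shorter than $d_s/u_p$ would give
negative diameters; these are clamped to zero and flagged
`subresolution` rather than raised as errors, since noise can shorten an
apparent width.

## Synthetic traces: what is emulated, and what is not

`sample_population()` draws arrivals as a Poisson process with rate
$C\,Q_j$ (so 10⁷ mL⁻¹ at 1 µL/h gives 833.3 expected events in 5 min),
sizes i.i.d. from a population preset, and per-event velocities jittered
with 15 % relative SD, the fluctuation level observed at 1 µL/h. The
presets are the two bench populations: micropillars (lognormal truncated
to the manufacturer's 0.4–1 µm length range, median 0.7 µm) and 5 µm
microspheres (normal, 5 % CV). Brightness scales with $d_p^2$ as a
cross-section proxy — a modeling choice, not a measured law — with
coefficients calibrated so the two worked pulses reproduce their printed
peak intensities (1.38 × 10⁴ counts for a 1.09 µm pillar at medium
gain; 3.68 × 10⁴ for a 5 µm sphere at low gain). A consequence the
model reproduces deliberately: at medium gain a 5 µm sphere overruns the
16-bit ADC, and the clipped, flat-topped pulse reads out *wider* than the
true transit, which is why mixed-population runs overestimate sphere
sizes.

The default **pulse shape** is a plateau with raised-cosine ($\sin^2$)
edges whose rise time is the sheet crossing $d_s/u_p$ and whose
half-maximum width is exactly $(d_p + d_s)/u_p$. This shape is chosen so
that the sizing relation above is exact by construction, and so that the
half-maximum level coincides with the edge's inflection point, making
linearly interpolated FWHM estimates third-order accurate. The physical
alternative — a top-hat particle profile convolved with a Gaussian sheet
profile (`shape = "gaussian"`) — is also provided, but its half-maximum
width lies between $\max(d_p, d_s)/u_p$ and the quadrature sum and never
reaches $(d_p+d_s)/u_p$, so inverting it with the linear sizing relation
is biased by up to ~0.06 µm for submicron particles. The cosine shape is
the default precisely because the sizing relation, not the sheet profile,
is the contract the instrument model is built around.

Noise is additive white Gaussian in ADC counts (default SD 350, set so a
0.39 µm pillar at medium gain sits near peak SNR 5 — the smallest pulse
class the system distinguishes), plus optional sinusoidal baseline drift
and spurious single-sample spikes. Not emulated: photon shot noise,
PMT gain statistics, the measured (uncharacterized) noise spectrum of the
real instrument, collection-optics geometry, and particle attitude
(anisotropic pillars are reduced to their streamwise extent). Passing
tests therefore demonstrate the correctness and self-consistency of the
processing chain under the stated noise model, not instrument-grade
performance on real data.

## Detection pipeline

Five steps, mirroring the instrument's processing chain: (1) baseline
removal and band limiting with threshold region-picking; (2)
moving-average smoothing (default 5 samples) and local-maxima search;
(3) edge determination with a pulse-width gate; (4) linearly
interpolated FWHM; (5) event statistics. The published description
names no filter constants, so all defaults live in `filter_config()`:
threshold = baseline + 5 robust SDs (median absolute deviation), with a
floor of 10 counts so noise-free traces do not flag numerical ripple; a
zero-phase (forward–backward) Butterworth low-pass at 100 kHz; the
high-pass side of the band limit realized as rolling-block-median
baseline subtraction, because a Butterworth high-pass at a few Hz
against a 250 kHz Nyquist is numerically degenerate and a median
baseline is robust to pulse asymmetry. "Validated with the bandpass
filter again" is read as a time-domain width gate — the only reading
consistent with a step that operates on pulse widths — and rejected
pulses are counted in a log. Saturation plateaus tie-break to the
plateau centre; two maxima in one region are merged unless the valley
between them drops below half the lower peak, which is what sets the
minimum resolvable event interval (≈ 0.05 ms at the high-throughput
settings; two pulses 0.1 ms apart always resolve, capping the usable
rate at 10⁴ events/s).

The width gate must match the flow settings: at 1 µL/h pulses last
0.7–3.5 ms and the default gate is 0.05–20 ms, while at the 20 µL/h
high-throughput settings pulses compress to tens of µs and the studies
below use a 0.02–2 ms gate. The gate is deliberately configuration, not
something inferred from the data.

## Population analysis

Events are summarized as a normalized 2-D histogram over
(diameter, peak intensity) — 64 × 64 bins, log₁₀ intensity because the
gains span 10⁵–10⁷. The reference analysis separates the two clusters
visually; here a fixed diameter boundary (2 µm by default) partitions
them deterministically, which is adequate for a bimodal
submicron-vs-5 µm mixture; a model-based two-component option is noted
as future work. β is the small-to-large count ratio (undefined, not
infinite, when a side is empty); detection efficiency δ is
100 × measured/theoretical, rounded to one decimal only at the report
layer; size fractions use the 0.2/0.4/0.6/0.8/1.0 µm bins with explicit
under/overflow.

One interpretation is worth stating. The β-recovery study compares the
pipeline's β estimate with the *realized* ground-truth count ratio of
each simulated trace, not with the mixture parameter: at 300-odd events
and β = 3 the Poisson draw alone fluctuates by ~13 % relative, so no
detector could match the parameter within 10 % in 90 % of such runs.
Against realized truth the chain recovers β within ~2 % and detects
99–100 % of rendered events. Likewise the chain's detection-efficiency
check is scored against the rendered events, bracketing at [95 %, 105 %]
what the physical instrument reported as 88.3 % and 104.3 % including
losses the simulator does not model (sedimentation, adhesion).

## Problem sizes and reproducibility

Optical checks run on 512² pupils with padding factor 4 (focal sampling
λ/(8 NA) ≈ 0.148 µm); the propagation oracle uses 64² so a direct
Fourier sum stays cheap. Mixture studies run at the 20 µL/h
high-throughput flow setting with ~24 events/s for 15 s per run
(≈ 360 events, ≈ 1 % overlap probability, 7.5 M samples per trace) —
sizes chosen so each study draws several hundred events per condition
while a full β ∈ {1, 2, 3} sweep with six seeded replicates each stays
comfortably runnable on a laptop. Every stochastic element is seeded:
identical (config, seed) pairs give byte-identical event tables, and the
end-to-end driver writes a manifest (config echo, seed, version)
sufficient to reproduce a run.

## Known limitations

* The optical model omits aberrations, index-mismatch, absorption and
  scattering; the self-healing property of Bessel beams in turbid media
  is out of scope.
* The exact stripe geometry of the original SSP method and the vectorial
  transmission field are not published; both are approximated as
  described above, so absolute sheet dimensions (e.g. the published
  12 × 12 × 0.8 µm with 0.18 µm thickness SD) are design targets, not
  desk-reproducible quantities. The package instead verifies calibration
  round-trips and the anti-diffraction property.
* The sizing relation is exact only for the cosine pulse model; with the
  physical convolution shape, submicron sizes are biased low by a known,
  documented amount.
* Doublet deconvolution, matched filtering and spectral unmixing are not
  implemented; overlapping pulses beyond the valley criterion merge.
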