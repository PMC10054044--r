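# adlscyto

Anti-diffraction light-sheet flow cytometry, in silico: optics synthesis,
trace simulation and pulse analysis in one R package.

## The problem

Conventional flow cytometers interrogate particles with a focused spot,
which discards most spatial information. Replacing the spot with a thin,
wide **anti-diffraction light sheet** — a parallel array of
Bessel–Gaussian beams written by a spatial light modulator (SLM) — lets a
microfluidic jet carry particles single-file through a plane ~0.8 µm
thick and ~12 µm wide. Each crossing yields a fluorescence pulse whose
full width at half maximum τ encodes the particle's streamwise size via

    dp = up · τ − ds

where `up` is the particle speed in the jet and `ds` the sheet thickness,
so a 500 kHz photomultiplier trace resolves sizes from O(100 nm) to
~10 µm at up to 10⁴ events/s. adlscyto implements the full chain for
people designing, tuning or stress-testing such instruments:

* **Optics** — SLM phase maps (blazed grating `Φ₁ = 2π(fx·Δx + fy·Δy)`,
  axicon `Φ₂ = 2π r tanα/λ`, stripe-split multiplexing of nine beams),
  focal fields via the Fourier form of the Debye integral
  `E = F[A e^{iΦ} p(θ) e^{i kz z}/cosθ]`, sheet metrology, and a
  calibration helper that tunes tanα to a target sheet thickness.
* **Microfluidics** — `Re = ρ Um Dh/µ` with `Dh = 2hw/(h+w)`, jet speed
  `up = k·Qall/(hw)`, and the sizing relation above.
* **Simulation** — Poisson arrivals at concentration × jet flow rate,
  per-event sizes/brightness/velocity jitter, PMT gain (10⁵/10⁶/10⁷),
  16-bit ADC with saturation, additive noise; fully seeded.
* **Detection** — five-step pipeline: baseline/band limiting with
  thresholding, moving-average smoothing and peak search, edge
  determination with a width gate, interpolated FWHM, sizing.
* **Population analysis** — 2-D probability density over (dp, Ifp),
  mixture ratio β, detection efficiency δ, size fractions.

## Worked example

Simulate two seconds of micropillars at bench conditions
(Qj = Qs = 1 µL/h, medium gain), detect and size the pulses, and
summarize:

```r
library(adlscyto)
cfg <- load_run_config(system.file("extdata", "demo.yaml",
                                   package = "adlscyto"))
res <- run_end_to_end(cfg, seed = 1)
res$report[c("n_events", "true_count", "efficiency_vs_truth_pct")]
#> $n_events
#> [1] 14
#> $true_count
#> [1] 14
#> $efficiency_vs_truth_pct
#> [1] 100
head(res$events, 3)
#>       time         fwhm      ifp           dp saturated subresolution
#> 1 0.123404 0.0009003346 9737.381 7.005577e-07     FALSE         FALSE
#> 2 0.353176 0.0006670488 5185.047 3.117480e-07     FALSE         FALSE
#> 3 0.403322 0.0008257774 4645.579 5.762957e-07     FALSE         FALSE
```

Every rendered crossing was recovered; the first event's 0.90 ms pulse
at 9.7 × 10³ counts sizes to 0.70 µm — a typical micropillar. The same
primitives answer design questions directly:

```r
geom <- channel_geometry()            # 50 x 10 um chamber
flow <- flow_config(1, 1)             # uL/h
reynolds_number(mean_channel_velocity(flow, geom),
                hydraulic_diameter(geom))
#> [1] 0.02777778                      # laminar
particle_diameter(mean_channel_velocity(flow, geom), 3.46e-3) * 1e6
#> [1] 4.966667                        # um, a 5 um microsphere

spec <- pupil_spec()                  # 473 nm, NA 0.4, 512^2 pupil
cal <- calibrate_axicon(spec)         # tanα for a 0.8 um sheet
cal$tan_alpha
#> [1] 0.003463071
```

A thin command-line front end wraps the same functions
(`inst/cli/adls.R`, verbs `optics`, `simulate`, `detect`, `analyze`,
`run`, `resolve-dt`).

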