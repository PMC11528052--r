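# patrace

Spatiotemporally resolved tracking of contrast-agent clearance in
photoacoustic tomography (PAT), for imaging scientists quantifying how an
injected probe washes into and out of organs such as the liver and kidneys.

The package implements four connected pieces:

* **Kinetics.** Relative enhancement
  `RE(t) = 100 (PA(t) − PA(0)) / PA(0)` is fitted with a fluence-corrected
  empirical uptake–washout model

  ```
  RE(t) = (A / F_ratio) [1 − exp(−α (t − t0))]^q exp(−β (t − t0)),  t ≥ t0
  ```

  (0 before `t0`), by bounded Levenberg–Marquardt with seeded multi-start.
  From the fitted curve it derives the peak time
  `T_max = t0 + log((qα + β)/β)/α`, the elimination half-life `T_1/2`
  (time after `T_max` to reach half peak), the rates `U_α = 60α` and
  `E_β = 60β` in min⁻¹, and the AUC over a named window. A Hampel filter
  removes respiratory spikes before fitting.
* **Fluence.** 2-D Monte Carlo photon transport (Henyey–Greenstein
  scattering, continuous absorption, Russian roulette, exact energy
  bookkeeping) on segmented optical tissue maps; the post/pre-injection
  fluence ratio `F_ratio`; fluence compensation of images with a division
  floor; and signal-to-background quantification.
* **Refocusing.** Coherence-factor-weighted synthetic aperture focusing
  for elevational scan stacks from a focused (virtual-detector)
  transducer, with `CF = PA_SAFT² / (N Σ |PA|²)` bounded in [0, 1], plus
  complementary frequency-band separation of the refocused volume into
  low-frequency tissue and high-frequency vascular components, envelope
  detection and FWHM resolution metrics.
* **Tracking.** The dynamic differential-imaging pipeline: baseline
  averaging, adaptive (Wiener-type) denoising, baseline subtraction,
  threshold suppression at a fraction of the series maximum, Frangi
  vesselness enhancement and pseudo-color overlay — with quantification
  always taken from raw frames, never from enhanced ones.

Synthetic phantom generators (defocused point-target stacks, kinetic
movies with breathing artifacts, optical tissue presets, and a
single-speed ring-array forward/back-projection pair) make every stage
testable without acquired data; each generator returns its ground truth.

## Worked example

Simulate a noisy kinetic movie with known ground truth, extract an ROI
curve, filter breathing spikes, fit the model and summarize clearance:

```r
library(patrace)

rois <- list(list(center = c(16, 16), radius = 6,
                  params = EMMParams(A = 60, t0 = 20, alpha = 0.05,
                                     beta = 0.004, q = 1)))
scene <- KineticScene(c(32L, 32L), rois, noiseSigma = 0.5,
                      breathingFraction = 0.1, nFrames = 150L,
                      frameInterval = 2, seed = 77)
movie <- makeKineticMovie(scene)

tc  <- roiTimecourse(movie, attr(movie, "truth")$masks[[1]], nBaseline = 8)
re  <- filterBreathingOutliers(relativeEnhancement(tc))
fit <- fitEMM(re)
fit
#> EMMFit (converged, n = 150, rss = 17.59)
#> EMMParams:
#>   A = 60.13 %, t0 = 20.15 s, alpha = 0.04789 /s, beta = 0.004012 /s, q = 0.9275, fRatio = 1

clearanceSummary(fit, tEnd = 298)
#> ClearanceSummary:
#>   RE_max (amplitude A/fRatio) = 60.13 %
#>   RE_max (curve peak)         = 45.04 %
#>   T_max = 72.17 s, T_1/2 = 192.8 s
#>   U_alpha = 2.873 /min, E_beta = 0.2407 /min
#>   AUC[0, 298 s] = 8967
```

The fitted parameters recover the generator truth (A = 60, t0 = 20 s,
α = 0.05 s⁻¹, β = 0.004 s⁻¹, q = 1) to within a few percent despite the
noise and breathing spikes. `RE_max` is reported under both conventions:
the model amplitude `A/F_ratio` and the strictly smaller fitted-curve
peak. `U_alpha`/`E_beta` are the fitted rates in min⁻¹, and the AUC
integrates the fitted curve over the stated window.

Refocusing a defocused stack:

```r
g  <- ScanGeometry(lf = 20, w = 8, dz = 0.1, fs = 40e6, c = 1.5, n0 = 300)
sc <- PointTargetScene(data.frame(depth_mm = 30, elev_mm = 10, amplitude = 1),
                       noiseSigma = 0.01, seed = 7)
st <- makePointTargetStack(sc, g, nScans = 201, nSamples = 1100)
res <- applySAFT(st)                      # paSaft, cf, paCfSaft
ns  <- round(attr(st, "truth")$arrival_sample[1])
measureFWHM(envelope(st@samples)[, ns], 0.1)
#> [1] 4.014461
measureFWHM(envelope(res@paCfSaft)[, ns], 0.1)
#> [1] 1.287851
```

A thin command-line front end over these functions ships in
`inst/cli/patrace` (subcommands `simulate`, `fit-emm`, `saft`, `fluence`,
`sbr`, `track`).

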