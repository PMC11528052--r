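---
title: "Tracking contrast clearance in photoacoustic tomography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking contrast clearance in photoacoustic tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patrace)
```

# The problem

Photoacoustic tomography (PAT) images optical absorption at ultrasound
resolution, deep enough to watch an injected contrast agent wash into and
out of the liver and kidneys of a small animal. Turning those movies into
pharmacokinetic numbers runs into three obstacles that this package
addresses in turn:

1. the PA amplitude at a pixel is proportional to the *local light
   fluence*, which changes when an absorbing agent perfuses the tissue, so
   raw enhancement curves confound kinetics with illumination;
2. a focused transducer scanned in elevation defocuses targets away from
   its focal plane, smearing them across neighboring scan positions in an
   hourglass pattern and ruining elevational resolution in stacked 3-D
   views;
3. respiratory motion injects large, sparse spikes into region-of-interest
   (ROI) time courses.

# The enhancement model

For an ROI with pre-injection mean intensity $PA(0) > 0$, relative
enhancement is

$$\mathrm{RE}(t) = \frac{PA(t) - PA(0)}{PA(0)} \times 100\,(\%).$$

The time course is fitted with an empirical uptake–washout model, scaled by
the fluence ratio $F_{ratio}$ (mean post-injection over mean pre-injection
fluence at the ROI, from Monte Carlo simulation):

$$\mathrm{RE}(t) = \begin{cases}
0 & 0 \le t < t_0 \\
\dfrac{A}{F_{ratio}}\left[1 - e^{-\alpha (t - t_0)}\right]^{q}
  e^{-\beta (t - t_0)} & t \ge t_0
\end{cases}$$

with amplitude $A > 0$ (% RE), rise time point $t_0$, uptake rate
$\alpha > 0$ (s$^{-1}$), excretion rate $\beta \ge 0$ (s$^{-1}$) and shape
exponent $q > 0$ that controls the early-uptake slope. $F_{ratio}$ is a
known, fixed scalar per ROI — it is never fitted jointly with the kinetics.

Derived clearance parameters (from the *fitted* curve):

* $T_{max} = t_0 + \alpha^{-1}\log\!\big((q\alpha + \beta)/\beta\big)$,
  the closed-form stationary point, clamped to the analysis window; with
  $\beta = 0$ the curve saturates and $T_{max}$ is reported at the window
  end.
* $T_{1/2}$: elapsed time after $T_{max}$ at which the curve reaches half
  its peak, solved by root bracketing on the fitted curve; infinite when
  $\beta = 0$ (no elimination phase) and reported as such, never as a
  number.
* $U_\alpha = 60\alpha$, $E_\beta = 60\beta$: the fitted rates reported in
  min$^{-1}$. We equate the "average uptake/excretion rate" with the
  model's $\alpha$ and $\beta$; they are the only rate constants in the
  model and no averaging recipe is available that would distinguish them.
  All internal computation is in seconds; the factor 60 is applied only at
  reporting.
* AUC over $[0, t_{end}]$ by adaptive quadrature of the fitted curve
  (`stats::integrate`, rel.tol 1e-9). A raw-trapezoid alternative
  (`rawAUC`) is provided because integrating raw samples is an equally
  defensible convention; the fitted-curve integral is the default since it
  is insensitive to outliers and sampling gaps.
* Two "maximum enhancement" conventions are reported side by side:
  `reMaxAmplitude` $= A/F_{ratio}$, the model's upper amplitude, and
  `reMaxCurve`, the fitted curve's actual peak, which is strictly smaller
  whenever $\beta > 0$. Conflating them overstates the peak, so both carry
  distinct names.

## Fitting

`fitEMM()` uses bounded Levenberg–Marquardt least squares (minpack.lm)
over $(A, t_0, \alpha, \beta, q)$ with bounds $A \in (0, 10\max RE]$,
$t_0 \in [\min t, t_{peak}]$, $\alpha \in (0, 100]$, $\beta \in [0, 10]$,
$q \in [0.1, 10]$. Initial values come from the data: $A$ from the observed
peak, $t_0$ from the first sample above 5% of peak, $\beta$ from the
log-linear tail slope, $\alpha$ from the 10–90% rise time, $q = 1$. Up to
five seeded multi-starts jitter those initials (lognormal, $\pm 35\%$); the
best converged solution wins and non-convergence is flagged, never silently
returned. The restart RNG is isolated from the global seed state.

## Breathing outliers

The respiration artifact model is a sparse multiplicative spike; the filter
is a Hampel filter (default window 11 samples, threshold 3 local scaled
MADs): a sample deviating from its running median by more than the
threshold is replaced by that median, everything else is untouched. We
implement the filter directly (rather than calling an existing one) so
that the first and last half-windows are also filtered with truncated
windows — respiratory spikes near the record ends are common, and the
reference implementation in `pracma` leaves those samples unfiltered. On
interior samples the two agree exactly (this is tested). The filter is an
identity on smooth monotone curves, which is what makes it safe to apply
before fitting.

# Monte Carlo fluence

`simulateFluence()` runs weighted photon transport on a 2-D labeled grid
(rows = depth, columns = lateral position), each label carrying
$\mu_a$ (mm$^{-1}$), $\mu_s$ (mm$^{-1}$) and anisotropy $g$:

* scattering free paths are sampled from the local $\mu_s$, with the
  remaining optical depth carried across cell boundaries;
* absorption attenuates the weight continuously along each ray segment
  ($w \mapsto w e^{-\mu_a \Delta s}$), and the per-cell fluence estimator
  is the closed-form track-length integral
  $w(1 - e^{-\mu_a \Delta s}) / (\mu_a \, A_{cell})$, which equals the
  deposited-weight estimator where $\mu_a > 0$ and degenerates smoothly to
  the path-length estimator $w \Delta s / A_{cell}$ where $\mu_a = 0$ — so
  purely scattering cells are still scored;
* deflection angles follow the 2-D Henyey–Greenstein phase function,
  sampled by exact CDF inversion
  $\theta = 2\arctan\!\big(\tfrac{1-g}{1+g}\tan(\pi(\xi - \tfrac12))\big)$;
* Russian roulette below weight $10^{-4}$ with survival probability 0.1,
  with exact weight accounting, so that
  launched = deposited + escaped + roulette adjustment holds to rounding
  (checked on every run by default);
* boundaries are index-matched (no Fresnel reflection): no refractive
  indices are available for the segmented maps, and the correction math
  being tested does not depend on them.

Three illumination patterns are provided: a pencil beam (top center), a
uniform top-edge beam, and a ring of N equally spaced inward-pointing
sources approximating ring illumination from a conical-lens pattern.
A useful property of the continuous-absorption scheme: in scattering-free
media the simulation reproduces Beer–Lambert attenuation with *zero*
variance, so the analytic cross-check is exact and the photon budget only
matters for scattering media.

`correctFrame()` divides an image by the fluence map with the divisor
floored at 1% of the maximum fluence (configurable): without the floor,
near-zero-fluence pixels amplify noise unboundedly. The consequence is that
compensation is only quantitative where fluence exceeds the floor; the
forward–inverse identity test excludes the floored region. The
signal-to-background ratio (`signalToBackground`) is defined as the linear
ratio of ROI means, the simplest convention consistent with "a ~50%
increase in SBR"-style statements.

# Synthetic-aperture refocusing

A focused transducer at focal distance $l_f$ with element height $w$ acts
as a virtual point detector at its focus. A target at one-way depth $l$
spreads over the elevational interval $z = \pm (l - l_f)\, w / (2 l_f)$,
i.e. over $z_s = \lfloor |z| / \Delta z \rfloor$ scan layers at step
$\Delta z$. With $r_i = |n_0 - n_i| \, c / f_s$ the range from a sample to
the focus, the defocused arrival at layer offset $j$ lags the apex by

$$\Delta t_j = \mathrm{sign}(l - l_f)\,\frac{\sqrt{r_i^2 + (j\Delta z)^2} - r_i}{c}.$$

`applySAFT()` sums the delayed neighbors $j \in [-\lfloor z_s/2 \rfloor,
+\lfloor z_s/2 \rfloor]$ per pixel (the literal reading of a
$-z_s/2 \ldots z_s/2$ summation with integer layers), with linear
fractional-delay interpolation (nearest-neighbor switchable) and plain
truncation at stack edges, never wrapping. Depth maps to samples by
one-way travel at $c$, the reception-only delay appropriate for
photoacoustic signals.

The coherence factor then down-weights incoherent pixels:

$$CF = \frac{PA_{SAFT}^2}{N \sum_j |PA(i+j, t - \Delta t_j)|^2}.$$

**Normalization choice.** The conventional written form divides by $z_s$,
but the sum contains $N = 2\lfloor z_s/2\rfloor + 1$ terms — for even
$z_s$ that is $z_s + 1$, so a fully coherent aperture gets $CF = N/z_s >
1$, and at stack edges the mismatch grows. We therefore normalize by $N$,
the count of terms actually summed, which bounds $CF \in [0,1]$ by
Cauchy–Schwarz; `cfNorm = "zs"` switches back to the written form (and the
test suite demonstrates the $> 1$ anomaly on a coherent fixture). Where the
denominator vanishes ($z_s = 0$ or an all-zero aperture) the pixel passes
through unchanged with $CF = 1$, so the degenerate aperture is an exact
identity.

`bandSplit()` performs the frequency-component separation of refocused
volumes: a complementary zero-phase spectral mask along the time axis, so
low + high reconstructs the input to floating tolerance and energy is
partitioned (Parseval). The default cutoff in examples is 2 MHz for a
5.5 MHz-centered transducer — tissue/organ signal is concentrated in the
low band, vascular detail in the high band; no principled universal cutoff
exists, so it is a plain argument. `envelope()` (FFT analytic-signal
magnitude) and `measureFWHM()` (linear interpolation at half maximum)
supply the resolution metric.

# Dynamic tracking pipeline

Display processing is deliberately separate from quantification: ROI time
courses (`roiTimecourse`) are always extracted from raw reconstructed
frames, while the following chain renders overlays.

1. `baselineImage`: pixelwise mean of the first $n$ frames (default 600,
   matching continuous-acquisition practice; desk-scale phantoms use ~20
   and say so explicitly).
2. `adaptiveDenoise`: Wiener-type local shrinkage toward the window mean
   by $\max(0, 1 - \nu/\sigma^2_{local})$ with noise power $\nu$ estimated
   as the mean local variance of the image itself (3×3 default window).
3. `differentialFrame`: frame − baseline, signed. The subtraction order is
   chosen so that post-injection enhancement is positive.
4. `thresholdSuppress`: zero pixels below 20% (default) of the maximum,
   where the reference maximum is taken over the *whole differential
   series*, not per frame — per-frame normalization would silently rescale
   late, faint frames; a per-frame mode remains available by passing each
   frame's own maximum.
5. `frangiVesselness`: standard 2-D Frangi response (scale-normalized
   Gaussian Hessian, $\beta = 0.5$, structure constant defaulting to half
   the maximum Hessian norm per scale, scales 1–4 px, bright-tube polarity
   only). The second-derivative kernels are DC-corrected so flat regions
   map to exactly zero.
6. `overlayPseudoColor`: signal alpha-blended over grayscale anatomy
   through a hot colormap; zero signal shows pure anatomy.

# What the phantoms emulate (and what they do not)

`makePointTargetStack` implements the virtual-detector forward model: each
target inserts a Gaussian tone burst (default 5.5 MHz, 0.6 fractional
bandwidth) along the hyperbolic arrival locus, restricted to the hourglass
acceptance cone, plus seeded Gaussian noise. It emulates geometric
defocusing only — no diffraction, element directivity beyond the acceptance
cone, acoustic attenuation or speed-of-sound heterogeneity. Passing the
resolution-recovery tests therefore shows the delay geometry and CF
weighting are right, not that in vivo stacks would refocus by the same
factor.

`makeKineticMovie` paints disk ROIs whose pixels follow
$\text{baseline}\times(1 + \mathrm{RE}_{true}(t)/100)$, with whole-frame
multiplicative breathing spikes (default 1.5×, one per 0.5 s period,
thinned to 10% of frames) and Gaussian noise. Real respiratory motion
deforms the image rather than scaling it; the spike model captures only
the effect on ROI means, which is the quantity the filter operates on.

`makeTissueMap` presets use literature-typical soft-tissue optical
properties (e.g. $\mu_s = 5\text{–}10$ mm$^{-1}$, $g = 0.9$,
$\mu_a = 0.01\text{–}0.3$ mm$^{-1}$); they are *not* measured organ values.
`ringForward`/`ringBackproject` are a single-speed-of-sound
delay-and-sum pair used as reconstruction plumbing for fixtures (default
fixture scale: radius 10 mm, 64 elements); half-time or dual-speed
reconstruction variants are out of scope.

# Numerical choices and problem sizes

* Fit tolerances: LM `ftol`/`ptol` 1e-12, max 500 iterations per start.
* $T_{1/2}$ root bracketing expands geometrically from the pure-exponential
  half-life $\log 2/\beta$; `uniroot` tol 1e-9 s.
* The degenerate inputs contract: all-zero curves, zero baselines, empty
  ROIs, shape mismatches and out-of-record targets raise errors naming the
  offending quantity rather than propagating NaNs.
* Test problem sizes are chosen to keep the full suite under a minute of
  CPU-bound work per module: stacks of 201 × 1100 samples, movies of
  32 × 32 × 150 frames, $10^5$–$10^6$ photons. These are the package's
  desk-scale study conditions; the statistical checks (median parameter
  recovery over 50 seeded curves, CF bounds over 100 random stacks) state
  their sample sizes in the tests themselves.
* File interchange uses Arrow IPC (lossless doubles plus named,
  unit-suffixed metadata such as `fs_hz`, `dz_mm`, `c_mm_per_us`),
  multi-page float TIFF for frame series, and CSV for 1-D curves.

# Known limitations

* The Monte Carlo is 2-D; out-of-plane scattering in real cross-sections
  redistributes fluence in ways a 2-D slab cannot capture. It is adequate
  for validating the compensation arithmetic and the $F_{ratio}$
  definition, not for dosimetry.
* $F_{ratio}$ is treated as one scalar per ROI; per-pixel correction would
  need co-registered pre/post fluence maps at matched noise.
* The SAFT model assumes a constant speed of sound and ignores transducer
  impulse response; CF weighting suppresses incoherent clutter but also
  darkens legitimately weak diffuse scatterers.
* Whether reported "average" uptake/excretion rates should be the fitted
  rate constants or some curve-averaged quantity is a convention choice;
  we use the fitted constants and label them as such.
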