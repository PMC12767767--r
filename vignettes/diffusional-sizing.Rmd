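---
title: "Diffusional sizing from microfluidic intensity profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusional sizing from microfluidic intensity profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffsizer)
```

## The measurement and its model

A fluorescently labeled analyte — a protein, or a multivalent protein complex
such as the postsynaptic GKAP–LC8 assemblies this method was developed for —
is focused by two buffer streams into a narrow band at the centerline of a
straight microfluidic channel. Under laminar flow the only lateral transport
is Brownian diffusion, so the cross-channel concentration profile spreads as
the band travels. A camera records cross-channel intensity profiles at marked
measurement points along the channel; each point corresponds to a transit time
$t = d / v$, where $d$ is its distance from the focusing intersection and $v$
the mean carrier speed.

For one-dimensional diffusion from a focused band, the concentration profile
at time $t$ is Gaussian. We parameterize components as

$$f(x) = a\, e^{-\left((x-b)/c\right)^2},$$

with amplitude $a$, center $b$ and width parameter $c$. Note that $c$ is the
*e-folding half-width*, not the probabilistic standard deviation: matching
this exponent against the diffusion kernel $e^{-x^2/4Dt}$ gives

$$c^2 = c_0^2 + 4 D t, \qquad a(t) = \frac{N}{\sqrt{\pi}\, c(t)},$$

so the slope of the squared width against transit time is $4D$ directly, and
$N = a\,c\sqrt{\pi}$ estimates the (intensity-weighted) particle count.
"Variance" throughout this package means this $c^2$. Keeping one convention
end to end is essential: mixing it with the $2\sigma^2$ convention silently
halves or doubles every diffusion coefficient and radius.

The Stokes–Einstein relation then converts the fitted diffusion coefficient to
a hydrodynamic radius,

$$D = \frac{k_B T}{6 \pi \eta r},$$

valid for approximately spherical particles at low Reynolds number. $T$ is the
absolute temperature and $\eta$ the medium viscosity; both come from the
measurement metadata.

The model rests on assumptions worth keeping in mind: plug flow (we use the
mean velocity `total flow / (h·w)`, with no parabolic-profile or
Taylor-dispersion correction), free diffusion (the band must stay well clear
of the sidewalls), and fluorescence proportional to concentration.

## From raw profiles to fitted widths

Each measurement point contributes a brightfield and a fluorescent trace
sampled along the same cross-channel vector.

1. **Crop** (`crop_profile`). If the recorded image was rotated to align the
   channel, the profile ends fall to zero where the sampling vector leaves the
   image. A band `mean ± sd` is laid around the raw brightfield trace and
   points are removed from each end until the first one above the band's lower
   limit. The statistics use the full raw trace — zeros included — with the
   population (n-denominator) standard deviation; the zeros depress the mean
   enough that the lower limit falls between zero pad and baseline.
2. **Wall location** (`locate_walls`). Starting from the fluorescent maximum,
   the brightfield trace is scanned toward both ends; the sample deviating
   most from the brightfield mean (minimum or maximum — walls can image bright
   or dark) marks each sidewall. A region of **twice** the displayed wall
   thickness, centered on each wall, is excluded, because a spike's apex does
   not reliably sit at the middle of the wall line. This yields the inside
   section and two outside sections.
3. **Baseline and area normalization** (`normalize_brightfield`,
   `normalize_fluorescent_set`). Brightfield traces are scaled so the inside
   mean sits at the 200-count standard. Fluorescent traces get a two-step
   normalization: first each baseline is scaled to the standard, then each
   trace is scaled by the ratio of the largest inside-channel integral in the
   set to its own, so all profiles enclose the same area (trapezoidal
   quadrature, outside sections ignored). The fluorescent step-1 baseline is
   estimated from the *outside* sections by default (`fluor_baseline_region`),
   because the inside contains the analyte signal; using the inside mean, as
   the brightfield step does, would fold signal into the baseline estimate.
   Area normalization is also what makes the analysis robust to slow signal
   drift, e.g. from particles accumulating on an untreated channel surface.
4. **Zero and center** (`zero_and_center`). The outside mean is subtracted
   (baseline to intensity 0) and `x` is shifted so the fluorescent peak sits
   at `x = 0`; the brightfield trace and wall centers shift rigidly. A trace
   whose inside peak does not clear three outside standard deviations is
   rejected as having no signal.

## Mixture fitting

Each centered fluorescent profile — inside section only — is fitted with a sum
of 1–8 Gaussian components by bounded nonlinear least squares
(Levenberg–Marquardt with box constraints) from randomized starts:
$a \sim U(0,\,2\max y)$, $b \sim U(-5, 5)$ μm, $c$ log-uniform within its
bounds. Restarting stops after `patience = 5` consecutive starts that fail to
improve the best RMSE (`sqrt(SSE/dfe)`); raising the patience beyond five
produced no meaningful RMSE gains in our runs. Component identity is fixed by
sorting on $c$, descending, before anything compares components.

Bounds encode the physics. Amplitudes are non-negative; centers stay within
±5 μm (the peak is observed to sit within 5 μm of the true center); widths are
positive and capped at 100 μm globally. From the second measurement point on,
the admissible radius range `[r_min, r_max]` (default 1 nm – 2 μm) is
translated through $c^2 = 4Dt$ into per-component width windows
$[\sqrt{c_{\text{prev}}^2 + s_{\min}\Delta t},\ \sqrt{c_{\text{prev}}^2 + s_{\max}\Delta t}]$,
which force every component to widen monotonically — without this, lingering
artifacts let fitted widths shrink between points.

Two degenerate situations get explicit treatment:

- **Saturation at the cap.** A spurious component (typical when the model
  order exceeds the true number of species) can sit at the 100 μm cap with
  near-zero amplitude. The mandatory minimum growth then has nowhere to go;
  treating that as a fatal error would kill every subsequent point, so the
  chain instead *pins* the component at the cap and logs the event
  (`sequential_sigma_bounds(on_saturation = "pin")`; the strict error remains
  the function's default contract). The pinned track has a stalled variance
  series and is reported as a failed component downstream rather than a
  radius.
- **Failed points.** If a point's fit fails outright, the chain accumulates
  $\Delta t$ and bounds the next point from the last successful fit; the point
  is recorded in the GoF table as failed, not fatal.

`gof_order_scan` tabulates SSE, RMSE, $R^2$ and adjusted $R^2$ over orders
1–8 at every point. On polydisperse data the jump from one to two components
is large and further components add nothing; the default order of 2 reflects
that, with the second component also absorbing the method's small-particle
bias. The scan is advisory — no automatic information-criterion selection.

## Sizing

The $k$-th widest component at each point forms track $k$. Each track's $c^2$
is regressed on transit time by ordinary least squares **with a free
intercept**: the focused band enters the channel at finite width, so the
intercept absorbs $c_0^2$ and the point-source form is recovered when it is
zero. Then $D = \text{slope}/4$ and the Stokes–Einstein radius follows.
Radii below the 1 nm floor are reported at the floor and flagged; components
whose slope is non-physical ($\le 0$) or so shallow that the radius exceeds
`r_max` (a stalled, pinned track) are reported as failures. For an order-2
fit the report carries the pair convention: the higher and the lower
approximate radius, plus their arithmetic mean as the single approximate
radius of the measurement. The higher value is the one that tracks reference
measurements best; the lower is biased toward the floor because smaller
particles diffuse disproportionately at a given flow rate.

## The simulator, and what passing it does (not) show

`simulate_profiles` generates measurement workbooks with known ground truth:
each species starts as a Gaussian band of width $c_0$ (default 10 μm) at the
channel center and spreads exactly as $c^2 = c_0^2 + 4Dt$, with amplitudes
scaling as $N/(c\sqrt{\pi})$ so mass is conserved and the particle-count
identity is testable. The brightfield trace is flat at the 200-count baseline
with a Gaussian bump at each sidewall; both traces get 30 zero-padded samples
per end to emulate rotation cropping; optional additive Gaussian noise and a
per-point multiplicative drift (surface-adsorption-like) complete the noise
model. The simulator refuses parameter sets where $3\sqrt{c_0^2 + 4Dt_\max}$
exceeds the half-width of the channel rather than silently truncating at the
walls, since the pipeline's free-diffusion model would be wrong there.

Default study conditions, chosen once: 300 μm × 20 μm channel, 20 μm wall
lines, eleven equidistant measurement points from 1 mm to 51 mm (a
three-design-unit device on a standard slide), steady-state pump rates
1 + 2×4 μL·min⁻¹ (mean speed 25 000 μm/s, transit times 0.04–2.04 s), water
at 25 °C (T = 298.15 K, η = 8.9×10⁻⁴ Pa·s), 2 μm sample spacing, and a
first-point peak of roughly 1000 counts over the 200-count baseline.

What the simulator does *not* emulate: pixelation and saturation, parabolic
flow profiles and Taylor dispersion, wall interactions, photobleaching,
focusing asymmetries, and non-Gaussian camera noise. Tests that pass on
simulator output therefore validate the *algorithms* — cropping, sectioning,
normalization, bounded fitting, tracking, regression, unit handling — under
the model's own assumptions; they do not by themselves certify accuracy on
real recordings, which is what reanalysis of deposited experimental workbooks
is for.

## Numerical choices

- Width floor ε = 10⁻³ μm; global cap 100 μm (observed to give the best
  approximations for samples of known size).
- Multistart improvement requires a relative RMSE gain above 10⁻¹²;
  non-finite optimizer results count as non-improving restarts.
- Fluorescent-maximum ties break toward the midpoint of the recorded vector.
- Trapezoidal quadrature on the uniform grid for all integrals.
- RMSE uses the `sqrt(SSE/dfe)` convention, `dfe = n − 3·order`.
- All randomness flows from one integer seed; reruns with the same
  configuration and seed reproduce every number bit-exactly.
- Workbook round trips preserve doubles exactly (`%.17g`).

## Problem sizes used in the checks

The packaged checks run the full pipeline on simulated sets of 11 points with
roughly 310 samples per trace: single species at 1.5/2/3/5 nm noiselessly
(recovery within 1%), twenty noisy replicates at 2% of-peak noise (within 15%
in at least 18), a 1.5 + 3 nm mixture at order 2 (both within 25%), and an
order 1–8 scan. The order-1 fitter is additionally cross-checked against an
exhaustive grid search over (a, b, c) on 31-point profiles — an independent
oracle that brackets the optimizer to within one grid step.

## Known limitations

- Accuracy degrades for larger particles (slower diffusion means less signal
  in the slope); near-micron sizes are out of reach of the linear
  variance–time model and would need a shape-library approach.
- The lower radius of the order-2 pair is biased toward the floor and should
  not be interpreted as a second species without corroboration.
- The plug-flow velocity uses the *total* volumetric flow (analyte plus both
  buffers) over the cross-section; all three streams share the main channel,
  and the analyte rate alone does not set the carrier speed.
- Closely similar species (width ratio near 1 at the first points) may stay
  merged in an order-2 fit; separation relies on the later, wider points.
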