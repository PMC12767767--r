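# diffsizer

Hydrodynamic radii of solute particles — proteins and their complexes — from
fluorescent intensity profiles recorded along a microfluidic focusing channel.

A labeled analyte is focused into a narrow band at the centerline of a
straight channel and carried along under laminar flow; lateral spreading is
then pure Brownian diffusion. Cross-channel intensity profiles recorded at
marked measurement points are fitted with bounded Gaussian mixtures,
parameterized as `f(x) = a exp(-((x - b)/c)^2)`, whose squared width grows
linearly with transit time:

    c²(t) = c₀² + 4 D t

The slope of the `c²`-versus-time regression gives the diffusion coefficient
`D = slope / 4`, the Stokes–Einstein relation

    D = kB T / (6 π η r)

converts it to a hydrodynamic radius `r`, and `N = a c √π` estimates the
intensity-weighted particle count. An order-2 mixture (the default) yields a
pair of radii per measurement — a higher and a lower approximation — with the
higher one tracking reference sizes best; the lower is biased toward small
values and is floored at 1 nm. No *a priori* size hypothesis is required
beyond the admissible range (1 nm – 2 μm by default).

The package covers the whole path from a measurement workbook to radii:
reading/writing the XLSX workbook dialect (metadata sheet plus one
position/brightfield/fluorescent sheet per measurement point), cropping
rotation artifacts, locating channel walls from the brightfield trace,
baseline and area normalization, bounded multistart mixture fitting with
sequentially widening width bounds, variance–time regression, and reporting —
plus a forward simulator that writes workbooks with known ground truth, so
every stage is testable without laboratory data.

## Worked example

Simulate a two-species analyte (1.5 nm + 3 nm), write it as a workbook, and
run the analysis:

```r
library(diffsizer)

ms <- simulate_profiles(species_mix(c(1.5, 3)),
                        noise = noise_model(additive_sd = 5, seed = 11))
write_measurement_workbook(ms, "two_species.xlsx")

fit <- diffsize("two_species.xlsx", diffsize_control(order = 2, seed = 5))
fit
#> Diffusional sizing fit
#>   11 measurement points, mixture order 2, seed 5
#>   mean particle speed 25000 um/s, transit 0.040-2.040 s
#>   approximate radius 2.126 nm (higher 2.773, lower 1.478)

coef(fit)
#>               slope intercept   D_um2_s radius_nm
#> component1 663.9224 111.02560 165.98060  1.478324
#> component2 353.9453  65.17415  88.48632  2.773006
```

The mean speed comes from the pump rates (1 + 2×4 μL/min) over the 20 × 300 μm
cross-section. Each component row is one variance–time line: the wider, faster
spreading component (rank 1) has the larger slope and hence the smaller
radius — here 1.48 nm against a 1.5 nm truth — while rank 2 gives 2.77 nm
against 3 nm. The intercepts absorb the squared initial width of the focused
band (c₀ = 10 μm in the simulator). `summary(fit)` adds per-point
goodness-of-fit, `plot(fit)` draws the variance–time regression,
`plot(fit, which = "profile", point = "P05")` overlays a fitted profile, and
`write_results(fit$report, "report.json", "json")` serializes everything with
provenance. `gof_order_scan(ms)` tabulates SSE/RMSE/R²/adjusted R² over
mixture orders 1–8 — on data like the above, going from one to two components
is a large gain and everything beyond is flat.

A thin command-line front end is installed with the package
(`inst/scripts/diffsizer`): `diffsizer run <workbook> --order 2 --omit P10`,
`diffsizer simulate --radius-nm 1.5,3 --out fixture.xlsx`,
`diffsizer gofscan <workbook> --max-order 8`.

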