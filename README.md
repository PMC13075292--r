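# mrbscan

Quantitation tools for **electrophoresis titration read out by a scanning
contactless conductivity detector** (sC⁴D). In this measurement, an analyte
(e.g. glucose) is converted enzymatically into a charged colored ion whose
*moving reaction boundary* (MRB) migrates along a microchip channel; the
boundary velocity grows with the logarithm of the analyte concentration, and
the boundary position is located — without optics — by sweeping a C⁴D
electrode pair along the channel and detecting the conductivity contrast
between the two zones.

The package is for analytical chemists and instrument developers who want to
simulate, process and calibrate such measurements:

- **Forward model** — conductivity from ionic composition
  (`σ = F Σ μᵢcᵢ`), sharp and diffuse (error-function) boundary profiles
  `σ(x,t) = σ₁ + (σ₂−σ₁)/2 · (1 + erf((x − x₀ − Ut)/(2√(Dt))))` with an
  optional leading-edge depletion trough, a sliding-window detector response
  `σ_D(t) = Σₖ fₖ σ_E(x(t)+δₖ)`, and a 1-D Nernst–Planck
  advection–diffusion–reaction simulator.
- **Signal processing** — baseline subtraction, 5-point moving average,
  and three boundary localizers (derivative "non-negative run" rule, trough
  argmin, pickup-cleared t₂ convention), with per-trace validity flags and
  the first-four-valid-fixes rule.
- **Quantitation** — `V_MRB` by OLS of position vs time,
  calibration `v = a·log₁₀C + b` (mm·min⁻¹ per decade), inverse prediction,
  limit of detection, RSD, spike recovery.
- **Synthetic experiments** — seeded generator reproducing the standard
  protocol (first scan at 7 min, 2-min interval, 4 scans, 1.0 mm/s) plus
  negative controls; bit-identical under a fixed seed.
- **CLI** — `simulate`, `detect`, `calibrate`, `quantify`, `recover`
  subcommands over YAML configs and a commented-CSV trace dialect
  (`inst/cli/mrbscan`).

## Worked example

Simulate a titration series at 0.5, 5 and 50 mM, localize the boundary in
the four scans of the 5 mM run, estimate its velocity, and read the
concentration back through the calibration law:

```r
library(mrbscan)

cfg <- experiment_config(concentrations = c(0.5, 5, 50),
                         noise_sd = 0.01, seed = 42)
exp <- generate_experiment(cfg)

fixes <- fixes_from_scan_series(exp$experiments[[2]]$traces, exp$baseline)
fixes
#>   clock_min t_boundary_s x_boundary_mm   method  quality valid
#> 1  7.120417        7.225         7.225 gradient 2.383374  TRUE
#> 2  9.126667        7.600         7.600 gradient 2.263801  TRUE
#> 3 11.132917        7.975         7.975 gradient 2.296342  TRUE
#> 4 13.138333        8.300         8.300 gradient 2.129452  TRUE

vel <- fit_velocity(fixes)
vel
#> Boundary velocity fit (n = 4)
#>   V_MRB = 0.1795 mm/min, intercept = 5.9571 mm, R^2 = 0.9989

conc <- c(0.2, 0.5, 1, 3.5, 10, 30, 50)
cal <- fit_calibration(conc, 0.272 * log10(conc) - 0.011)
predict_concentration(cal, vel$v_mrb)
#> [1] 5.014513
```

The four fixes advance linearly (≈ 0.18 mm/min); inverting the calibration
returns 5.01 mM for the nominally 5 mM sample — the end-to-end error is the
combined effect of localization granularity (one sample = 25 µm) and the 2 %
trace noise.

Boundary-free negative controls are rejected rather than quantified:

```r
nc <- generate_negative_control(cfg)
fixes_from_scan_series(nc$traces, nc$baseline)
#> Error: only 0 valid fixes; need at least 3
```

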