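---
title: "Moving-boundary quantitation with a scanning conductivity detector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moving-boundary quantitation with a scanning conductivity detector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrbscan)
```

## The measurement principle

Electrophoresis titration encodes an analyte concentration in the migration
velocity of a *moving reaction boundary* (MRB): in the glucose model system,
the analyte is converted enzymatically to the colored cation CV⁺, which
migrates toward the cathode and is neutralized where it meets the
counter-migrating titrant OH⁻. The interface between the CV⁺ zone and the
alkaline buffer zone — the MRB — moves at a velocity $V_\mathrm{MRB}$ that
grows with the logarithm of the analyte concentration, and the position of the
boundary can be read out *without optics* by scanning a capacitively coupled
contactless conductivity detector (C⁴D) along the channel: the two zones have
different ionic compositions, hence different conductivities.

`mrbscan` implements the full quantitation chain for this class of
measurement:

1. a **forward model** of the conductivity profile $\sigma_E(x, t)$ around the
   boundary and of the detector trace a scan produces from it,
2. the **signal-processing** pipeline that turns raw scan traces into
   per-scan boundary positions ("fixes"),
3. **quantitation**: velocity estimation, log-linear calibration, limit of
   detection, repeatability and spike recovery,
4. a seeded **synthetic-experiment generator**, so the whole workflow runs and
   is testable without hardware, and
5. a small **CLI** binding the stages into reproducible runs.

## Forward model

**Conductivity law.** For fully dissociated, singly charged ions,
$\sigma = F \sum_i \mu_i c_i$ over cations and anions
(`conductivity_from_species()`), with $F$ the Faraday constant, $\mu_i$ the
electrophoretic mobility and $c_i$ the molar concentration. A table of
literature mobilities and diffusion coefficients for K⁺, Na⁺, Cl⁻, acetate,
OH⁻ and CV⁺ ships in `extdata/ion_defaults.csv`; the CV⁺ entries are
order-of-magnitude estimates for a bulky organic cation, flagged as such, and
everything is overridable.

**Boundary profiles.** Two idealizations are provided. The sharp-boundary
picture assumes conductivity $\sigma_1$ behind the boundary (the CV⁺ zone,
lower conductivity), $\sigma_2$ ahead, and a linear transition between two
edges (`linear_boundary_profile()`). The diffuse-front picture treats the
boundary as an advected error-function front,

$$c_\mathrm{CV}(x,t) = c_0\left(1 - \operatorname{erf}
  \frac{x - x_0 - U t}{2\sqrt{D t}}\right), \qquad
\sigma_E(x,t) = \sigma_1 + \frac{\sigma_2-\sigma_1}{2}\left(1 +
  \operatorname{erf}\frac{x - x_0 - U t}{2\sqrt{D t}}\right),$$

implemented in `erf_front_concentration()` and `erf_conductivity_profile()`.
The conductivity expression is written in the *asymptote-consistent* form: it
tends to $\sigma_1$ far behind and $\sigma_2$ far ahead of the boundary and
equals $(\sigma_1+\sigma_2)/2$ at the midpoint $x = x_0 + Ut$, which is what
the zone definitions require. (A form in which the same expression is written
as $\sigma_1 + \frac{\sigma_2-\sigma_1}{2}\operatorname{erf}(\cdot)$ appears
in parts of the literature; its asymptotes $\sigma_1 \pm
(\sigma_2-\sigma_1)/2$ contradict the zone values, so we document it but do
not implement it.)

Superimposed on the front, the state can carry two localized Gaussian
features: a **depletion trough** at the leading edge — the reaction zone,
where OH⁻ is consumed and CV⁺ has not yet arrived, leaving few carriers — and
a smaller anion-**accumulation bump** further ahead. Both are off by default
in the raw profile functions and parameterized (amplitude, width, offset);
the synthetic generator turns the trough on because it is the signature real
scans show.

**Signed velocity.** $U$ may be negative: below the flux-balance
concentration the titrant flux exceeds the analyte-ion flux and the boundary
retreats toward the anode. With the default calibration law (below), the zero
crossing sits near 1.1 mM, so the 0.2 mM standard genuinely runs backwards.
The boundary forms at `x_origin` (default 6 mm, a few millimeters past the
solution–gel interface), keeping all positions inside the 24 mm channel.

**Detector response.** A scan converts the spatial profile into a
time-domain trace. Treating the boundary as stationary during one scan (the
1.0 mm s⁻¹ scan speed is two to three orders of magnitude above $|U|$), the
detector output at sample time $t$ is the discrete sliding-window transform

$$\sigma_D(t) = \sum_k f_k\, \sigma_E\!\left(x_\mathrm{start} + v_\mathrm{scan} t
  + \delta_k\right),$$

with $f$ the spatial sensitivity of the electrode pair discretized over
offsets $\delta_k$ (`scan_response()`, `electrode_window()`). Three window
shapes are available: a normalized unipolar trapezoid spanning the
actuator–gap–pickup footprint (2.5 + 1.5 + 2.5 mm), a bipolar differential
variant for antiparallel pick-up wiring, and a delta (point) response.

**Which window is realistic?** The geometric footprint suggests the
trapezoid, but an instrument-resolution analysis argues otherwise. Noise in
C⁴D enters mostly in the electronics, i.e. *after* the spatial averaging; a
6.5 mm window therefore smears the boundary signature without attenuating the
noise, and with white noise at 2 % of the zone step the derivative/argmin
localizers below then cannot do better than several tenths of a millimeter
per fix. Real scanning C⁴D systems, however, achieve per-concentration
repeatabilities that imply fix precision of a few tens of micrometers — only
possible if the effective axial response is far narrower than the footprint,
as expected when the sensed impedance is dominated by the solution column in
the inter-electrode gap. The synthetic generator therefore defaults to the
delta response, with the footprint windows retained as options; all window
shapes are exercised by the tests.

**Nernst–Planck simulator.** `simulate_electromigration()` complements the
closed-form profiles with an explicit finite-difference solution of 1-D
advection–diffusion per species, optional fast CV⁺/OH⁻ annihilation
(removing the two one-for-one per cell), fixed-reservoir or closed (no-flux)
ends, and stability guards on the advection Courant number
($|v|\,\Delta t/\Delta x \le 1$) and the diffusion number
($D\,\Delta t/\Delta x^2 \le 0.5$) that name the violated bound. The upwind
advection scheme is diffusive but conservative: closed-channel mass is
conserved to floating-point accuracy, and an advected front's half-height
point moves at $\mu E$.

## Signal processing

Per scan, the pipeline (`fixes_from_scan_series()`) is:

1. **Baseline subtraction** (`subtract_baseline()`): the background scan of
   the pre-filled chip is registered on the detector *position* axis,
   resampled onto the sample trace's grid by linear interpolation (no
   warping), and subtracted. Traces with different scan speeds are rejected.
2. **Smoothing** (`moving_average()`): centered 5-point moving average; at
   the edges the window shrinks symmetrically, so the output length equals
   the input length and no data are fabricated.
3. **Localization**, one of three conventions:
   - `gradient` (default): forward-difference derivative; global maximum
     (earliest on ties); the maximal contiguous run of indices with
     derivative $\ge -\varepsilon$ (default $\varepsilon = 0$) containing
     that maximum; the run's first sample is the detection time. On the
     trough signature this is the sample where the signal stops falling —
     the trough bottom.
   - `trough`: earliest global minimum of the filtered signal.
   - `t2`: trough time with a fixed geometric offset subtracted from the
     window-center position, for instruments whose signal peaks when the
     pick-up electrode has fully cleared the boundary.

   The detected time maps to position via
   $x_b = x_\mathrm{start} + v_\mathrm{scan} t_b$, and the fix clock is
   the scan-start clock plus $t_b$.
4. **Validity**: each fix carries a quality (peak derivative, or trough
   depth measured from the trace maximum). With `quality_min = NULL` the
   validity floor is derived per trace from its own noise scale (a robust
   MAD estimate of the first differences): 5× the expected derivative noise
   for the gradient method, 25× the per-sample noise for the trough depth.
   These multipliers sit above the expected extreme values of pure noise on
   a ~10³-sample trace, so boundary-free scans are flagged invalid while the
   boundary signature (depth of order the full zone step) clears the floor
   by an order of magnitude. A fixed threshold can be supplied instead.
5. **Selection**: at most the first four valid fixes are retained, and at
   least three are required — otherwise an insufficient-data error is
   raised.

One bias is worth knowing about: the fix clock uses the detection time
(scan start + $t_b$), which is the right convention for real data, but the
generator freezes the profile at the scan start; the resulting velocity
underestimate is below 1 % at the default schedule and is visible in the
recovery numbers.

## Quantitation

`fit_velocity()` fits boundary position (mm) against clock (min) by ordinary
least squares; the slope is $V_\mathrm{MRB}$ (mm min⁻¹). `fit_calibration()`
fits $v = a \log_{10} C + b$; the slope unit is mm min⁻¹ per decade. The
base-10 logarithm is a deliberate choice (standard in analytical
calibration; the 0.2–50 mM working range spans ~2.4 decades). Both return
classed objects with `print`, `coef`, `summary`, `predict`, `plot` (and
`residuals` for the velocity fit). `predict_concentration()` inverts the
calibration, $C = 10^{(v-b)/a}$, flagging extrapolation outside the
calibrated range.

`compute_lod()` implements the $k\,\mathrm{SD(blank)}$ inverse-prediction
convention, $\mathrm{LOD} = 10^{((v_\mathrm{blank} + k\,s_\mathrm{blank}) -
b)/a}$ with $k = 3$ and $v_\mathrm{blank} = 0$ by default. A caveat is
documented rather than hidden: with a log-linear law whose zero-velocity
crossing lies *inside* the working range (here ≈ 1.1 mM), the
$v_\mathrm{blank}=0$ default names that crossing, not a vanishing amount —
with the default convention the computed value is ≈ 1.2 mM. Detection limits
for this chemistry therefore depend on the blank convention chosen, and both
$k$ and $v_\mathrm{blank}$ are explicit parameters.

`compute_rsd()` is the sample (n−1) relative standard deviation;
`compute_recovery()` is $100 \cdot \mathrm{found}/\mathrm{spiked}$, reported
to one decimal. Recoveries are always recomputed from the found and spiked
values rather than transcribed, because printed tables occasionally round
inconsistently (e.g. 147.8/150 is 98.5 % at one decimal even if a table
prints 98.6 %). Per-concentration repeatability is reported as the RSD of
the replicate *found concentrations*: an RSD of the velocity itself is
ill-defined near the zero-crossing concentration, where the mean velocity
vanishes.

## The synthetic generator

`generate_experiment()` emulates one complete run per concentration under
the standard protocol: background scan first, then scans at 7, 9, 11, 13 min
(2 min interval), 1.0 mm s⁻¹, with the boundary velocity drawn from the
calibration law ($a = 0.272$, $b = -0.011$ by default). Instrument defaults
were fixed once, from the physics and the resolution analysis above, and are
not tuned per run: zones $\sigma_1 = 0.5$, $\sigma_2 = 1.0$ S m⁻¹; front
diffusion $D = 5\times10^{-10}$ m² s⁻¹; depletion trough of amplitude
0.65 S m⁻¹ and width 0.2 mm centered on the boundary (the reaction sink
nearly exhausts carriers locally, and a moving reaction front self-sharpens
against diffusion); 40 Hz sampling; additive white noise with SD 0.01 —
2 % of the zone step. Slow polynomial drift (with scan-to-scan amplitude
wander) and impulsive spikes are available but off by default, as no noise
characterization beyond "smooth traces" is available to emulate.
`generate_negative_control()` produces boundary-free scans that the pipeline
must reject. All randomness derives from the mandatory seed; identical
configurations give bit-identical output, including through the CSV dialect.

The generator refuses configurations whose boundary speed reaches the scan
speed (the detector could never overtake the boundary — the catch-up
constraint) and configurations whose boundary leaves the scannable region
during the schedule.

**What passing tests do and do not show.** The generator reproduces the
*geometry and statistics* of the measurement: schedule, kinematics, the
trough signature, concentration-dependent signed velocities, white noise.
It does not model enzyme kinetics (concentration enters only through the
velocity law), electroosmotic or thermal drift spectra, capacitive-coupling
circuit response, channel-to-channel variability, or scan return time
(resets are idealized as instantaneous). Agreement on synthetic data
validates the algorithms, not the chemistry.

## Numerical choices and tie-breaks

- Spatial grid 10 µm over 24 mm for rendered profiles; linear interpolation
  everywhere; window weights discretized at 10 µm.
- Ties: earliest index wins, both for the maximum derivative and for equal
  trough minima.
- Degenerate inputs raise classed errors (`mrbscan_domain_error`,
  `mrbscan_config_error`, `mrbscan_insufficient_data`,
  `mrbscan_no_boundary`, `mrbscan_io_error`); the CLI maps these to exit
  codes 2/3/4.
- Calibration slopes with $|a| < 10^{-12}$ are treated as degenerate for
  inverse prediction.
- Test and acceptance problem sizes: triplicate experiments at seven
  concentrations (84 scans of ~960 samples) for the calibration-quality
  check; velocity grids of 4–5 points for locator round trips; Nernst–Planck
  runs on 51–201 cells for a few hundred steps. These sizes keep the full
  suite in the low seconds while leaving every claim exercised end to end.

## Worked example

```{r}
cfg <- experiment_config(concentrations = c(0.5, 5, 50),
                         noise_sd = 0.01, seed = 42)
exp <- generate_experiment(cfg)
fixes <- fixes_from_scan_series(exp$experiments[[2]]$traces, exp$baseline)
fixes
vel <- fit_velocity(fixes)
vel
# against the generating calibration law
cal <- fit_calibration(c(0.2, 0.5, 1, 3.5, 10, 30, 50),
                       0.272 * log10(c(0.2, 0.5, 1, 3.5, 10, 30, 50)) - 0.011)
predict_concentration(cal, vel$v_mrb)
```

## Known limitations

- The trapezoid/bipolar footprint windows make the stock localizers
  imprecise at realistic noise; matched-filter or correlation localization
  would use the available information better and is a natural extension.
- The LOD convention question above: for boundary chemistries with an
  interior zero-velocity crossing, a detection limit defined against a
  lowest-standard blank would be more meaningful than the $v_\mathrm{blank}
  = 0$ default.
- The Nernst–Planck stepper is first-order upwind (numerically diffusive)
  and does not enforce electroneutrality or solve the Poisson equation;
  it is a mechanistic illustration, not a quantitative electrolyte model.
- Two-channel chips are handled as batch processing; no crosstalk model.
```
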