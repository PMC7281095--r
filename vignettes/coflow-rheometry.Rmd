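---
title: "Co-flow microfluidic rheometry: model, estimators and synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-flow microfluidic rheometry: model, estimators and synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coflowr)
```

## The measurement principle

A blood sample (test fluid) and a reference fluid of known viscosity flow
side by side through one shallow rectangular channel. Because both streams
share the same pressure gradient, the position of their interface encodes
the viscosity ratio: a more viscous test fluid occupies a wider lane. The
interface fraction is `alpha = W_B / W`, the blood-filled width over the
channel width, and its linearizing transform is `beta = 1/(1 - alpha)`.

Three properties are read off one periodic on-off experiment of the test
pump (the reference pump runs continuously):

* **viscosity** from the steady interface while both pumps run at the same
  rate;
* **viscoelasticity** from the exponential relaxation of the interface
  after each pump transition, interpreted through a linear Maxwell model;
* **RBC aggregation** from the rise of the ROI-averaged image intensity
  after the flow has stalled.

## The fluidic-circuit model

The two streams are modelled as a discrete circuit: flow sources for the
two pumps, lumped lane resistances, and a compliance `C_T` contributed by
the air cavity trapped in the syringe (plus tubing and device elasticity).
Treating the interface as a virtual wall and compensating that
simplification with a CFD-fitted quartic correction factor
`C_f(alpha)` gives the nonlinear governing equation

```
C_T R_WT d/dt [ C_f/(1 - alpha) ] + C_f alpha/(1 - alpha) = (Q_T/Q_R)(mu_T/mu_R)
```

with the lane resistance `R_WT = 12 mu_T L_cc / (W_T h^3)`. Two
linearization coefficients, `F1 = 1.112` and `F2 = 1.129`, reduce this to
a first-order linear ODE in `beta`,

```
lambda d beta/dt + beta = 1 + (1/F2)(Q_T/Q_R)(mu_T/mu_R),
lambda = F1 F2 C_T R_WT,
```

whose steady state inverts to the viscosity formula
`mu_B = mu_R (beta - 1) F2` at matched flow rates, and whose transients are
single exponentials with time constant `lambda` (`lambda_on` after pump
start, `lambda_off` after pump stop — the two differ in practice and are
fitted separately).

`simulate_linear()` integrates the linear ODE piecewise over the on/off
segments (adaptive `lsoda`, relative tolerance 1e-8, output on the
protocol's 0.5 s grid); every segment has an analytic exponential solution,
which the test suite uses as an independent oracle at 1e-6 relative
tolerance. `simulate_nonlinear()` integrates the nonlinear form with
`y = C_f/(1 - alpha)` as the state.

### The non-invertible fold of the correction polynomial

The printed quartic makes `y(alpha)` non-monotone near the lower end of its
fitted validity interval (0.1, 0.9): `y` has a shallow minimum near
`alpha ~ 0.203` with the default coefficients. Below that fold the state
cannot be inverted and the implied dynamics change sign — an artifact of
the polynomial fit, not of the physics. The nonlinear simulator therefore
inverts `y` on the monotone increasing branch only and reports its usable
interval (about 0.2 to 0.9) in its error messages; trajectories that decay
through the fold (for example a long pump-off hold, whose steady state is
`alpha = 0`) stop with a domain error naming the failure time. The
linearized model has no such restriction and is the primary analysis path.

### Where the lane width enters

Whether the resistance formula should use the full channel width or the
blood-lane width is not determined by the model as stated; the package
defaults to the full width `W` and exposes `W_lane` as a parameter of
`channel_geometry()`. Only the product `C_T R_WT` enters the time constant,
and the primary parameterization of transients is `(lambda_on, lambda_off)`
directly — fitted, not derived — so this choice is inert for all headline
analyses. The co-flow channel length `L_cc` (default 10 mm, a typical value
for such devices) matters only when converting an explicit compliance value
with `lambda_from_compliance()`.

## Image quantification

`interface_from_frame()` binarizes the ROI at the Otsu threshold, removes
isolated misclassified pixels with a single 3x3 morphological opening, and
measures the blood-filled width as the contiguous run of blood-class pixels
from the blood-inlet wall, averaged along the channel. Blood is the darker
phase by default (bright-field); both the side and the polarity are flags,
since raising the illumination for RBC imaging can invert the contrast.
The estimate is invariant to linear intensity rescaling because the Otsu
threshold scales with the histogram. A between-class-variance floor
(default 1e-3 in normalized units) rejects ROIs without a bimodal
histogram; an exactly uniform ROI is reported as "no blood" with a warning
rather than an error, since that is the legitimate all-reference state.

`channel_width()` applies the same thresholding to a filled-channel frame
and averages the wall-to-wall distance along the channel; it is used for
the channel-deformation check (the pressure at the maximum flow rate of
2 mL/h widens the soft channel by about 1.3%, below the 2% bound within
which the nominal width is used).

`intensity_trace()` is the plain ROI mean per frame — no flat-field or
illumination correction is applied because none is part of the measurement
definition; AI results are shift-invariant anyway (see below).

## Estimators

* `fit_time_constant()`: damped nonlinear least squares of
  `beta0 + beta1 exp(-t/lambda)` on a fixed window after each transition —
  60 s after turn-off, 20 s after turn-on by default (turn-on transients
  converge faster). Initialization is `beta0` = last sample, `beta1` =
  first - last, `lambda` = window/5, with `lambda` bounded in
  `(dt/10, 10 window]`; an amplitude below 1e-3 is a degenerate fit and is
  refused rather than returned.
* `viscosity_constant_flow()` / `viscosity_varying_flow()`: the steady
  formula and its flow-corrected form `mu_R (beta - 1) F2 (Q_R/Q_B)`; the
  corrected branch excludes samples below `Q_min = 0.1` mL/h, where the
  correction amplifies interface noise without bound.
* `elasticity()`: `G_B = mu_B / lambda` in mPa. `lambda_off` is the
  representative time constant (it correlates tightly with `lambda_on`);
  the turn-on constant is used only in the varying-flow branch. Reported
  in mPa: a stress unit is the only dimensionally consistent reading of a
  viscosity divided by a time.
* `find_t0()` + `aggregation_index()`: the post-stop intensity minimum
  (earliest tie wins) and the trapezoid integral of the rise above it over
  a span `ts` (default 60 s), divided by `ts`. The trapezoid rule is the
  lowest-order unbiased rule on a uniform grid; the integrand is signed.
  AI is invariant to adding a constant to the trace and linear in its
  gain, so raw gray levels are adequate.
* `fit_velocity_calibration()` / `velocity_to_flow()`: a through-origin
  linear map between ROI-averaged velocity and the set flow rate.
* `power_law_fit()`: `mu = mu0 gamma_dot^(n-1)` (the standard
  Ostwald-de Waele apparent-viscosity convention), fitted in log-log
  space.

The pipeline (`analyze_experiment()`) sequences these per period and
refuses to report viscosity from a steady sub-window (last 25% of the on
segment, 30 s for the default protocol) whose relative `beta` drift
exceeds 1%. The drift is measured between the means of the leading and
trailing 20% of the sub-window: a two-sample endpoint difference would be
dominated by sampling noise at realistic noise levels. The 25% sub-window
comfortably exceeds all off time constants observed without a blood-side
air cavity; `recommend_period()` encodes the planning rule
`T >= 2 (t_steady + 2 lambda_off)` for conditions where it does not. For
the t0 search on measured data the intensity trace is first smoothed with
a short centered rolling mean (5 samples) and the minimum is then refined
on the raw trace within one smoothing window, which removes the argmin
bias a one-sided rise induces under smoothing.

## The synthetic-data generator

The generator stands in for the microscope-plus-syringe-pump experiment so
every pipeline stage is testable without blood. Its defaults are the study
conditions: period 240 s, duty 0.5, 0.5 s sampling, matched flow rates of
0.5 mL/h, reference viscosity 1 cP, per-diluent test viscosities
2.95/3.53/5.89/4.59 cP, velocity calibration slopes 2.0732 (PBS) and
2.6287 (dextran), and a PBS-like transient pair
`lambda_on = 3.2 s, lambda_off = 5.9 s` (consistent with the Maxwell pair
`mu_B = 2.95 cP, G_B = 0.5 mPa`).

* **Interface**: the linear simulation plus Gaussian noise with sd equal
  to 1% of the on-segment amplitude.
* **Velocity**: the calibration slope times an effective flow rate that
  relaxes toward each segment's set point with that segment's time
  constant.
* **Intensity**: a first-order relaxation toward a phase-dependent target
  — baseline while pumping, a small dip (2 gray) while decaying flow
  persists, and a saturating exponential rise of amplitude 10 gray (time
  scale 20 s) once the velocity falls below a 0.2 mm/s gate. The rise is
  exactly exponential from the gate, so the aggregation index over
  `[t_gate, t_gate + ts]` has the closed form
  `A (1 - (tau/ts)(1 - e^{-ts/tau}))` used as ground truth. Intensity
  noise defaults to 0.1 gray: the ROI mean over 240x200 pixels averages
  per-pixel camera noise down to ~0.02 gray, so 0.1 gray is a
  conservative ROI-level floor.
* **Images**: two-level frames split at `round(alpha W_px)` with optional
  1-px edge blur and per-pixel Gaussian noise (default sd 5 gray).

Everything is deterministic given the scenario seed, and every generator
attaches its ground truth as an attribute. What the generator does **not**
model — and what passing tests therefore cannot certify on real data —
includes pump ramp dynamics (switching is an instantaneous step),
correlated PIV estimation noise, camera shot noise and illumination drift,
cell sedimentation, and any mechanistic description of aggregate formation
or of how a given air-cavity volume maps to compliance. In particular the
observed *decrease* of `lambda_off` with a reference-side air cavity is an
empirical finding the package reproduces only phenomenologically (by
setting the time constants), not mechanistically.

## Numerical choices and degenerate inputs

* ODE integration: `lsoda`, rtol 1e-8 / atol 1e-10, interpolated onto the
  protocol grid; per-segment closed forms are the solver oracle.
* Nonlinear state inversion: bracketed root finding (`uniroot`, tol
  1e-12) on the monotone branch; leaving the branch raises an error
  naming the time.
* Otsu thresholding on a 256-bin histogram of the normalized ROI; ties in
  `find_t0()` break to the earliest time; `beta = 1` viscosity (zero-width
  lane) is returned as 0 with a warning rather than an error.
* Units: user-facing um, cP, mL/h, s; all internal computation in SI.
  `G_B` is always reported in mPa.
* Problem sizes in the test and acceptance runs are desk-scale by design:
  one to three 240 s periods at 0.5 s sampling, 20-seed Monte Carlo
  batches, 40-frame image stacks of 50x200 px. These sizes put every
  Monte Carlo tolerance comfortably above its standard error while
  keeping the full suite in seconds.

## Known limitations

* The blood-lane hemodynamics are lumped: no cell-free layer, no
  hematocrit dependence beyond what the supplied viscosities encode, no
  Fåhræus–Lindqvist correction (the equivalent-diameter helper exists to
  reason about that comparison, not to correct for it).
* The nonlinear model is unusable below the fold of the fitted
  correction polynomial (`alpha` below ~0.2), including every pump-off
  steady state; the linearized model is the analysis path there.
* Aggregation truth values are generator constructs; on real data the
  intensity kinetics need not be a single exponential, and `ts` must be
  chosen (default 60 s) since the index scales with it.
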