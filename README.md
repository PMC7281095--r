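# coflowr

Blood rheology from co-flowing-stream microfluidic experiments.

A blood sample and a reference fluid of known viscosity flow side by side
through one shallow rectangular channel; because both streams share the
same pressure gradient, the position of their interface encodes the
viscosity ratio. Driving the blood pump in a periodic on-off pattern while
the reference pump runs continuously yields, from a single experiment:

* **viscosity** — at matched flow rates the steady interface gives
  `μ_B = μ_R (β − 1) F₂`, where `β = 1/(1 − α)` linearizes the interface
  fraction `α = W_B/W` and `F₂ = 1.129` is a linearization constant of the
  underlying fluidic-circuit model;
* **viscoelasticity** — the interface relaxes exponentially after each
  pump transition with time constant `λ = F₁F₂·C_T·R_WT` set by the air
  compliance of the syringe; a linear Maxwell model converts it to an
  elastic modulus `G_B = μ_B/λ_off`;
* **RBC aggregation** — after flow stops, red-cell aggregation raises the
  ROI-averaged image intensity; the index is the time-normalized integral
  `AI = (1/t_s) ∫ (⟨I(t)⟩ − ⟨I(t₀)⟩) dt` above the post-stop minimum at
  `t₀`.

The package implements the full measurement chain: the lumped
fluidic-circuit model (nonlinear and linearized) and its simulators, Otsu
interface/width extraction from grayscale image stacks, all estimators
(time constants, constant- and varying-flow viscosity, shear rate,
equivalent diameter, elasticity, aggregation index, velocity-flow
calibration, power-law summary), a protocol-locked synthetic-data
generator with analytic ground truth, and a per-period analysis pipeline.
Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on results.

## Worked example

Simulate a PBS-like experiment (three 240 s periods, duty 0.5, matched
0.5 mL/h flows, λ_on = 3.2 s, λ_off = 5.9 s, μ_T = 2.95 cP, 1% interface
noise) and analyze it per period:

```r
library(coflowr)

sc    <- synthetic_scenario(seed = 42)
beta  <- gen_beta_trace(sc)
inten <- gen_intensity_trace(sc)

res <- analyze_experiment(beta, list(protocol = sc$protocol, mu_R = 1),
                          intensity = inten)
res
#> <rheo_summary> per-period blood rheology
#> # A tibble: 3 × 8
#>   period mu_B_cP lambda_off_s lambda_on_s G_B_mPa    AI converged note
#> *  <int>   <dbl>        <dbl>       <dbl>   <dbl> <dbl> <lgl>     <chr>
#> 1      1    2.95         5.84        3.22   0.504  7.06 TRUE      ""
#> 2      2    2.96         5.79        3.18   0.512  6.83 TRUE      ""
#> 3      3    2.95         5.86        3.23   0.503  6.89 TRUE      ""
#> mean +/- sd: mu_B = 2.95 +/- 0.009 cP, lambda_off = 5.83 +/- 0.035 s,
#>   G_B = 0.506 +/- 0.0046 mPa, AI = 6.93 +/- 0.12
```

Read: each period independently recovers the true viscosity (2.95 cP), the
off time constant (5.9 s), the Maxwell elasticity implied by the pair
(0.5 mPa), and the aggregation index of the generated intensity rise
(analytic truth 6.83 gray for amplitude 10, τ = 20 s, t_s = 60 s). A single
transient fit looks like:

```r
fit_time_constant(beta, window = c(120, 180))
#> <coflow_expfit> y = 1.0082 + 2.6124 * exp(-t/5.8444), lambda = 5.844 s
#>   window [120, 180] s, n = 121, rms residual = 0.0208
```

`autoplot(beta)`, `autoplot(res)` and `autoplot(fit)` draw the trace, the
per-period summary and the fit overlay. A thin CLI over the same functions
lives at `inst/cli/coflow.R` (`simulate` / `synth` / `analyze`
subcommands).

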