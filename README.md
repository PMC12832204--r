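# ednadrift

Decay kinetics and Lagrangian dispersal of marine environmental DNA (eDNA).

## The problem

Marine eDNA surveys are usually interpreted through a single-phase
exponential decay assumption: once shed, the signal decays at a constant
first-order rate *k*. Tank experiments frequently disagree — measured copy
numbers often decline in two phases (**biphasic** decay: a fast early loss
followed by a much slower tail) or even **rise** for several hours before
declining (**delayed** decay, as intracellular DNA becomes progressively
detectable). Which kinetics you assume changes how far from its source, and
for how long, an eDNA plume remains detectable.

`ednadrift` is for researchers who model eDNA transport or analyze decay
experiments. It provides, as one tested R package:

* **decay kinetics** — the first-order model `C(t) = C00 e^(-k t)`, the
  two-exponential mixture `C(t) = C01 e^(-k1 t) + C02 e^(-k2 t)` (biphasic
  when both amplitudes are positive, delayed when one is negative), the
  temperature law `k(T) = 0.0419 e^(0.0776 T)` h⁻¹, half-lives by
  bisection, nonlinear fitting with tank-level offsets and AIC/R²
  comparison, and rule-based pattern classification;
* **a 2-D Lagrangian particle tracker** — RK4 advection (3-min step) on
  gridded currents, random-walk diffusion (`K = 1` m² s⁻¹), per-step
  binomial survival `exp(-k Δt)`, and four decay scenarios (exponential,
  biphasic 70%@0.50 h⁻¹ + 30%@0.013 h⁻¹, delayed with hourly 20% particle
  division for 6 h ≈ threefold growth, and no decay);
* **event-based dispersal metrics** — alive counts, centre of mass, mean
  displacement, dispersion, convex-hull area, within-hull density, and
  scenario-vs-reference relative densities;
* **variance decomposition** — standardized metrics analyzed by a
  three-way Type III ANOVA (scenario × metric × hour, release-occasion
  blocking) with partial η² effect sizes;
* **synthetic data generators** for everything above: tidal flow fields
  with realistic speed envelopes (a dynamic site, 0.01–2.4 m s⁻¹, and a
  quiet site, 0.01–0.6 m s⁻¹) and tank-experiment style concentration
  series — so the full pipeline runs and is tested without any downloads.

See the vignette (`vignettes/edna-decay-dispersal.Rmd`) for the models,
assumptions and design choices.

## Worked example

Simulate a temperature-crossed tank experiment with a delayed-decay truth,
fit both decay models, and classify the pattern:

```r
library(ednadrift)

design <- decay_series_design(noise_cv = 0.2)     # 3 temps x 2 tanks x 8 times x 3 reps
series <- generate_decay_series(design, seed = 1)

fit1 <- fit_decay_models(series, "first")
fit2 <- fit_decay_models(series, "second")
fit2
#> Decay model fit (second order)
#>   n = 144 observations, 15 parameters
#>   AIC = 1399.50, R2 = 0.928
#>  temperature_C parameter      estimate
#>             13       C01  -238.2359632
#>             13        k1     1.3159675
#>             13       C02   329.0712267
#>             13        k2     0.1085392
#>             20       C01  -520.6612730
#>             20        k1     0.6298271
#>             20       C02   619.5010400
#>             20        k2     0.2729837
#>             27       C01 -9934.7387748
#>             27        k1     0.5474470
#>             27       C02 10020.6524621
#>             27        k2     0.5297723
fit1$AIC
#> [1] 1588.52
classify_decay_pattern(series)
#> [1] "delayed"
```

The mixture fit wins by AIC (1399.5 vs 1588.5) and recovers the delayed
shape at 13 and 20 °C: a negative fast component (the early rise) on top of
a slow phase whose rate (0.109, 0.273 h⁻¹) tracks the temperature law. At
27 °C the two fitted rates nearly coincide with huge offsetting
amplitudes — the mixture collapsing onto a single exponential, i.e. no
delayed signature at the warm end.

Scenario-level quantities come from the same kinetics:

```r
temperature_decay_rate(temperature_decay_law(), 12)   # January water
#> [1] 0.1063201
half_life(second_order_params(0.7, 0.5, 0.3, 0.013)) # biphasic mixture
#> [1] 2.414893
```

To see what the kinetics do to a plume, run the tracker — here a small
January release at the quiet site:

```r
cfg <- pipeline_config(
  scenarios = c("exponential", "delayed", "no_decay"),
  max_events_per_combo = 6,
  sim = simulation_config(n_particles = 1000, tracking_horizon_h = 24),
  seed = 1)
res <- run_pipeline(cfg, quiet = TRUE)
rd <- res$relative_density$quiet$delayed  # per-hour median + 20-80% band vs exponential
round(rd[rd$hour %in% c(1, 3, 6, 12, 24), ], 2)
#>    hour median  p20  p80 n_events
#> 2     1   1.30 1.27 1.37        6
#> 4     3   1.89 1.72 2.01        6
#> 7     6   4.04 3.97 4.36        6
#> 13   12   3.87 3.75 3.93        6
#> 25   24   3.65 3.54 3.80        6
```

The delayed scenario's median density climbs to about four times the
exponential reference by hour 6 (the end of the division phase) and stays
well above 1 all day. In `res$anova$quiet`, the `metric:hour` interaction
dominates the Type III decomposition (partial η² = 0.85 at this scale) —
each dispersal metric follows its own diurnal course.

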