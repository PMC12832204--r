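---
title: "Decay kinetics and Lagrangian dispersal of marine eDNA: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decay kinetics and Lagrangian dispersal of marine eDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Environmental DNA (eDNA) surveys infer the presence and abundance of
organisms from DNA recovered in water samples. Interpreting such data in the
sea requires knowing how quickly the signal fades once shed — and most
transport models assume a single first-order (exponential) loss. Empirical
decay experiments, however, often show richer kinetics: a *biphasic* decline
(a fast early phase followed by a much slower one, consistent with rapidly
degraded extracellular DNA coexisting with protected, cell-bound DNA) or a
*delayed* decline (an initial **rise** in measured copies over the first
hours, consistent with intracellular DNA becoming progressively detectable
as cells lyse). `ednadrift` provides the pieces needed to ask what these
alternative kinetics do to the dispersal and detectability of an eDNA plume:
decay-model fitting and classification for tank-experiment data, a
scenario-driven Lagrangian particle tracker, event-based dispersal metrics,
and a variance decomposition of those metrics.

All inputs are synthetic and generated by the package itself, so every stage
is testable offline; the generators are first-class, documented code, not
test scaffolding.

## Decay kinetics

Two concentration models are supported. The first-order model is

$$C(t) = C_{00}\, e^{-k t},$$

with `C00` the initial concentration (copies µL⁻¹) and `k` the decay rate
(h⁻¹). The second-order model is the two-exponential mixture

$$C(t) = C_{01}\, e^{-k_1 t} + C_{02}\, e^{-k_2 t},$$

which covers both biphasic decay (both amplitudes positive, `k1 >> k2`) and
delayed decay (one negative amplitude, producing an early rise) with only
four parameters and a smooth phase transition. The package stores components
ordered so that `k1 >= k2` (the fast phase first); this is a reporting
convention, not a constraint on the fit.

Temperature enters through the exponential rate law

$$k(T) = a\, e^{b T}, \qquad a = 0.0419\ \mathrm{h^{-1}},\ b = 0.0776\ \mathrm{°C^{-1}},$$

the median decay–temperature relationship for teleost fish eDNA. It is used
as the rate of the exponential scenario and of the post-rise phase of the
delayed scenario, and as the default slow-phase truth of the synthetic
experiment generator.

`half_life()` reports the smallest time at which the expected curve falls
to half its initial value, found by geometric bracketing plus bisection to
an absolute tolerance of 1e-6 h, with an `Inf` sentinel when the curve
never crosses (zero rates, the no-decay scenario). For a biphasic mixture
the half-life reflects the *mixture*, not the fast phase alone: the default
0.7/0.3 mixture at rates 0.50/0.013 h⁻¹ halves at about 2.4 h even though
its fast component alone would halve in 1.4 h.

### Fitting

`fit_decay_models()` fits either model to replicate-level concentration
data, one parameter set per temperature. Tank identity (biological
replicate) enters as a multiplicative offset on the amplitude — equivalently
an additive offset on log-amplitude — constrained to sum to zero across
tanks within each temperature. With two tanks this plays the role of a
random intercept; a deliberate simplification, since the estimated offset
and a BLUP are practically indistinguishable at two levels, and it keeps the
fit deterministic. The offsets are *profiled out*: for a fixed curve the
least-squares multiplier of each tank has a closed form, so the optimizer
alternates between a Levenberg–Marquardt step on the curve parameters
(`minpack.lm::nlsLM`, rates bounded below by zero) and the exact offset
update. Each block step weakly decreases the residual sum of squares, which
avoids the gradient singularities that arise when amplitude-like offsets are
estimated jointly with amplitudes.

Robustness to the mixture model's multimodality comes from multi-start:
a log-spaced grid over candidate rate pairs (with amplitudes initialized by
linear least squares at those rates) plus dedicated delayed-shape starts
with a negative fast amplitude; at least 12 starts per temperature for the
first-order model and 14 for the second-order model. The best
residual-sum-of-squares solution wins.

Model comparison uses AIC under a Gaussian observation model on the pooled
residuals (`-2 logLik + 2(p+1)`, counting fixed-effect parameters, free
offsets, and the residual variance) and `R² = 1 − SSR/SST` on the pooled
observations. A plain squared-error R² was chosen because pseudo-R²
definitions for nonlinear mixed fits are not unique; with the fixed-offset
formulation the plain definition is exact.

Outlier handling is explicit only: `exclude_times` removes named time
points before fitting and records them in the result. No automatic
detection is attempted — removing a suspect late sample is an analyst's
judgement, and an automatic rule would hide it.

### Classification

`classify_decay_pattern()` encodes the visual screening rules used to
categorize decay curves:

* **delayed** if the group-mean concentration within the early window
  (default 6 h) rises more than 25% above the initial mean;
* otherwise **biphasic** if the two-component fit has both amplitudes
  positive (each at least 1% of the initial concentration, to reject
  numerically spurious components), a fast/slow rate ratio of at least 5,
  and a better AIC than the first-order fit;
* otherwise **exponential**;
* **unclassifiable** when fewer than two distinct sampling times fall in
  the early window — without early-phase samples the non-exponential
  signatures are invisible, which is why the companion
  `summarize_decay_review()` reports the exponential share over
  early-sampling studies only.

## The synthetic tank experiment

`decay_series_design()` mirrors a temperature-crossed aquarium experiment:
three temperatures (13, 20, 27 °C), two tanks (A, B), eight sampling times
(0, 0.5, 1, 2, 4, 6, 23, 26 h), three technical replicates per filter.
Three generator choices are worth stating:

* **Noise** is multiplicative lognormal with a default coefficient of
  variation of 0.3, mean-corrected so the expected value follows the truth
  curve. Replicated ddPCR concentration measurements scatter roughly
  proportionally to their level, and fitted decay curves in such
  experiments typically leave half the variance unexplained; CV 0.3
  reproduces that regime. Property tests use CV 0.2.
* **Tank offset**: tank A exceeds tank B by a factor of 2 in expectation
  (persistent level differences between nominally identical tanks are
  common), applied symmetrically (`sqrt(2)` up/down) so the geometric mean
  across tanks still follows the truth.
* **Truth**: the default `delayed_decay_truth()` is
  `C(t) = (C0 + B) e^{-k(T) t} - B e^{-k_1 t}` with `C0 = 100` copies µL⁻¹,
  `B = 250`, `k1 = 1` h⁻¹ and the slow rate from the temperature law. At 13
  and 20 °C the curve more than doubles before declining and is still above
  `C0` at 6 h; at 27 °C the fast ambient decay erodes the rise, so the
  delayed signature fades at the warm end — the transition the fitting and
  classification machinery must cope with.

With `noise_cv = 0` and `replicate_offset = 1` the generator returns an
exact evaluation of the truth model; that noiseless limit anchors the
exact-recovery tests.

## Lagrangian transport

`run_event()` releases `n_particles` (default 10,000, roughly the shedding
of a single fish over the tracking window) at the surface and integrates
2-D trajectories for 24 h:

* **Advection**: classical fourth-order Runge–Kutta with a fixed 3-minute
  step on the bilinearly (space) and linearly (time) interpolated velocity
  field. Metres convert to degrees by local equirectangular scaling with
  `cos(latitude)` at the particle and an Earth radius of 6,371 km.
* **Diffusion**: a random-walk step per axis with standard deviation
  `sqrt(2 K dt)`, `K = 1` m² s⁻¹ by default — the scale-appropriate
  horizontal diffusivity for a ~500 m grid. The resulting 2-D mean squared
  displacement grows as `4Kt`, which the tests verify directly.
* **Decay**: a per-step Bernoulli survival draw with probability
  `exp(-k Δt)`. This is the semigroup-consistent choice: survival composes
  exactly across steps, so per-step draws at 3 minutes reproduce the hourly
  closed form without discretization bias (unlike `1 − kΔt`).
* **Domain exits**: a particle whose advection stage or diffusion kick
  leaves the grid is marked dead permanently — "alive" means neither
  decayed nor exited. No reflecting boundaries.

The four decay scenarios:

* `no_decay` — reference; isolates advection and diffusion.
* `exponential` — rate `k(T)` with the temperature read from the field at
  the particle's position each step.
* `biphasic` — a one-off exact-count split: `round(0.7 N)` particles get
  0.50 h⁻¹ and the rest 0.013 h⁻¹, each keeping its rate for the whole run.
  The exact-count split (rather than per-particle Bernoulli assignment)
  matches the intended proportions exactly and removes a variance source.
* `delayed` — during the first 6 h, no decay draws; at each whole hour,
  `round(0.2 N_alive)` particles chosen without replacement are duplicated
  in place (children inherit position and future dynamics), compounding to
  `1.2^6 ≈ 2.99` — a threefold rise. Afterwards the scenario decays like
  `exponential`. Treating the growth phase as division-only is a modelling
  choice: the rise in measured concentrations is represented entirely by
  particle multiplication, with ambient decay subsumed in the observed
  net rise.

Each event draws from its own RNG stream derived from the master seed and
the event id, so any single event is reproducible in isolation and event
order does not matter.

`build_release_schedule()` enumerates releases at a fixed cadence covering
whole months: 2-hourly releases over January and September of one year give
372 + 360 = 732 events per site–scenario pair, 2,928 over four scenarios —
29.28 million trajectories at the default particle count. Release occasions
shared across scenarios keep a common `release_id`; that identifier, not
the per-scenario event id, is the blocking unit of the downstream ANOVA.

## Synthetic forcing

`generate_flow_field()` emulates the statistical character of surface
currents at two contrasting coastal sites rather than any particular
circulation solution:

* a **rotating semidiurnal tidal ellipse** (period 12.42 h) — a rotary
  current reproduces the back-and-forth excursion of macrotidal coasts
  while keeping the velocity field divergence-free;
* a **spring–neap envelope** (period ≈ 14.8 d) modulating the tidal
  amplitude between neap and spring values;
* a weak uniform **residual flow** in a seeded random direction;
* a weak stationary, **divergence-free spatial perturbation** from a
  sinusoidal streamfunction spanning the grid (peak 0.02 m s⁻¹), which
  vanishes at the grid centre. Its correlation length is of the order of
  the grid extent, so interpolation and RK4 see a smooth field, and the
  release point (grid centre, via `site_grid()`) feels exactly the
  uniform components — which makes the sites' speed envelopes exact at the
  release point.

The `dynamic` preset (48.05° N, 5.05° W) combines a 2.25 m s⁻¹ spring tidal
amplitude, a 0.10 m s⁻¹ neap amplitude and a 0.05 m s⁻¹ residual, so
monthly speeds at the release point span about 0.05–2.3 m s⁻¹ inside a
declared 0.01–2.4 m s⁻¹ envelope; the `quiet` preset (47.68° N, 4.51° W)
spans about 0.04–0.56 m s⁻¹ inside 0.01–0.6 m s⁻¹. Temperature is spatially
uniform and monthly constant — 12 °C in January and 18 °C in September with
the default mean (14 °C) and seasonal half-range (4 °C). No single
simulation temperature is canonical for this kind of study; 12 °C makes the
exponential scenario's January half-life about 6.5 h, a mid-range value for
temperate fish eDNA.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real coastal flows: bathymetry and coastlines (no land
mask, no shear against a boundary), baroclinic and wind-driven variability,
spatially structured temperature, realistic kinetic-energy spectra, or
vertical motion. The generator's purpose is to provide forcing with the
right speed envelopes, periodicities and smoothness so the *relative*
behaviour of the decay scenarios can be studied; absolute dispersal
distances and their event-to-event variability inherit the simplifications.

## Dispersal metrics

`compute_metrics_table()` summarizes each (scenario, event, hour) from the
alive particles only:

* `n_alive` — particles neither decayed nor exited;
* centre of mass — the coordinate-wise arithmetic mean of longitude and
  latitude (a planar mean; adequate for footprints of tens of km);
* mean displacement — haversine distance (radius 6,371 km, via `geosphere`)
  from the release point to the centre of mass;
* dispersion — mean squared haversine distance of particles from the
  centre of mass (km²);
* convex-hull area — positions projected on a local tangent plane about
  the centre of mass, hull vertices from `chull`, area by the shoelace
  (triangle-fan) formula (km²); fewer than three non-collinear points give
  zero;
* density — `n_alive / hull_area` (km⁻²), with an `NA` sentinel when the
  hull area is zero.

Hours with zero alive particles keep their rows with `NA` sentinels —
downstream code must see that an event died, not a shortened series.
`relative_density()` divides each event's density by the across-event
median density of a reference scenario at the same hour and reports the
per-hour median and 20–80% band; because the geometry of the plume is
nearly scenario-independent, these ratios essentially expose the survival
curves, which is what makes them the right lens for comparing decay
scenarios.

## Variance decomposition

`standardize_metrics()` centres and scales each metric to z-scores. The
default grouping is per metric × site: standardizing within scenario as
well would remove exactly the scenario differences the analysis is meant to
measure, so the literal per-scenario variant is available
(`metric_site_scenario`) but not the default; the grouping used is recorded
on the output. Constant groups become zeros with a flag rather than an
error.

`decompose_variance()` fits `z ~ scenario * metric * hour + release`, with
hour since release as an unordered factor (the metrics' diurnal courses are
strongly non-linear, and a factor puts no shape assumption on them) and the
release occasion as a *fixed* blocking factor. A mixed model with a random
release intercept is the textbook formulation; the fixed-block
approximation was chosen because it is deterministic, closed-form, and on
balanced schedules gives the same Type III sums of squares for the fixed
terms. Type III tests come from `car::Anova` under sum-to-zero contrasts;
partial η² is `SS_term / (SS_term + SS_residual)`. Hour 0 is excluded by
the pipeline (its hull and density are degenerate by construction), and
factors reduced to a single level are dropped so degenerate fixtures
collapse to lower-way ANOVAs. Missing cells raise an error naming the
cells; p-values are reported raw (no multiplicity correction is applied, as
none is standard for a single planned decomposition).

## Numerical choices, sizes, limitations

* Half-life bisection tolerance 1e-6 h; Earth radius 6,371 km everywhere;
  equal-rate or zero-amplitude mixtures are accepted and reduce exactly to
  the single exponential.
* Second-order component ordering `k1 >= k2` breaks the label-switching
  tie; equalities are left as fitted.
* The test suite runs the tracker at reduced scale — typically 50 release
  occasions × 2,000 particles for the scenario-ordering check, 10,000
  particles for single-event closed-form checks, and 50 seeded synthetic
  experiments for the model-selection operating characteristics. These
  sizes keep the full suite comfortably reproducible on a laptop while
  leaving the statistical tolerances (3 binomial standard errors, 10% on
  the diffusion slope, 25% on slow-rate recovery) meaningful.
* Known limitations: 2-D surface transport only (no vertical structure or
  migration); instantaneous point releases (no continuous shedding);
  detection probability is not modelled — density is a proxy for
  detectability, not a detection model; the fixed-block ANOVA
  underestimates nothing on balanced designs but is not a substitute for a
  mixed model on badly unbalanced ones.
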