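---
title: "One-compartment biokinetic modelling with biokin: models, estimation and model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-compartment biokinetic modelling with biokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biokin)
```

## The models

`biokin` models the whole-body concentration $C_{org}(t)$ of a contaminant
(typically an engineered nanomaterial) in a soil or aquatic invertebrate
during a two-phase experiment: the organisms sit in a contaminated medium of
concentration $C_{exp}$ until the transfer time $t_e$, then in a clean medium
until $t_{total}$.

The plain one-compartment (OC) model has an uptake rate constant $k_1$
(L kg$^{-1}$ h$^{-1}$ for aqueous exposure, kg kg$^{-1}$ d$^{-1}$ for soil)
and a first-order elimination rate constant $k_2$ (per time unit):

$$C_{org}(t) = C_0 + C_{exp}\,\frac{k_1}{k_2}\left(1 - e^{-k_2 t}\right),
\qquad 0 \le t \le t_e,$$
$$C_{org}(t) = C_0 + C_{exp}\,\frac{k_1}{k_2}
\left(e^{-k_2 (t - t_e)} - e^{-k_2 t}\right), \qquad t > t_e.$$

Many organisms sequester part of the absorbed material in tissue
(hepatopancreas in isopods, chloragogenous tissue in annelids) where it is
not subject to first-order elimination.  The stored-fraction model (OC-SF)
adds a dimensionless fraction $SF \in [0, 1]$, applied in *both* phases: a
share $SF$ of the influx accrues linearly and remains inert, while the
remaining $(1 - SF)$ follows the OC dynamics:

$$C_{org}(t) = C_0 + SF\,C_{exp} k_1 t
 + (1 - SF)\,C_{exp}\frac{k_1}{k_2}\left(1 - e^{-k_2 t}\right),
 \qquad 0 \le t \le t_e,$$

with $t$ frozen at $t_e$ in the stored term after the transfer.  At $SF = 0$
the OC-SF model reduces to OC exactly; the two branch expressions agree at
$t = t_e$, and the implementation evaluates a single expression
$C_0 + SF\,C_{exp}k_1\min(t, t_e) + (1-SF)\,C_{exp}(k_1/k_2)
(e^{-k_2\max(t - t_e,\,0)} - e^{-k_2 t})$ that makes the continuity
automatic.  Conventions worth stating:

* $t = t_e$ is assigned to the uptake branch (both branches agree there, so
  this is labelling only).
* Units are metadata: $k_1$ and $k_2$ are interpreted in whatever time and
  medium units the scenario declares; no conversion is ever performed.
* The background burden $C_0$ is treated as inert and is retained
  indefinitely in the elimination phase, exactly as the closed forms above
  state.
* $k_2 = 0$ is rejected rather than replaced by its linear limit; the
  fitting bounds keep $k_2 \ge 0.001$ anyway.
* The simulation grid is $0, \Delta t, 2\Delta t, \dots$ up to $t_{total}$,
  with $t_e$ appended when it is not on the grid so the kink is always
  represented.  ($t_{total}$ itself is not appended when $\Delta t$ does not
  divide it; the grid is documented as covering "up to" the horizon.)

```{r example}
sc <- exposure_scenario(c_exposure = 1, t_e = 48, t_total = 96, dt = 4,
                        time_unit = "hour", medium_unit = "mg/L")
p <- kinetic_params(k1 = 0.426, k2 = 0.155, sf = 0.086)
head(simulate_series("OC-SF", p, sc))
steady_state_burden(kinetic_params(0.196, 0.033), sc)
```

## Estimation: genetic-algorithm least squares

`fit_model()` estimates $(k_1, k_2)$ or $(k_1, k_2, SF)$ by minimising the
residual sum of squares over a bounded box with a real-coded genetic
algorithm, single-threaded so that a fixed seed reproduces the fit bit for
bit.  The operating point mirrors the deployed web tool: a population of
1000, a steady-fitness stopping rule of 300 generations, and $k_2$ bounded
in $[0.001, 100]$ per time unit — roughly thirty-fold beyond the largest
elimination constants reported for invertebrate/nanomaterial systems, so the
bound is a numerical guard, not a scientific constraint.  Choices the tool's
description leaves open were fixed as follows and are configurable through
`fit_config()`:

* **Objective.** Unweighted least squares; replicate observations enter
  individually.  (Weighted fits, e.g. by replicate dispersion, are out of
  scope.)
* **Encoding and initialisation.** One real-valued gene per parameter,
  uniformly initialised within the bounds.  Genes are evolved on the linear
  scale; the decades-spanning nature of the rate constants is handled by the
  mutation operators rather than by a log re-encoding.
* **Selection and crossover.** Tournament selection of size 3;
  single-point crossover with probability 0.5 per pair.
* **$k_1$ bounds.** $[0, 10^6]$ by default: published uptake constants
  reach $\sim 3\times 10^4$, and the default applies the same
  safety-margin philosophy as the $k_2$ bound.
* **Mutation** (probability 0.2 per gene) mixes three moves: a uniform
  resample within the bounds (global exploration), a multiplicative
  log-normal step (scale-aware search across decades), and an additive
  Gaussian step whose scale is the spread of the elite 5 % of the
  population, which anneals as the fit converges.
* **Correlated moves.** The least-squares surface of these models has
  narrow curved valleys along constant $k_1/k_2$ (the uptake plateau) and,
  for OC-SF, constant $SF\,k_1$ (the stored-accrual slope).  Axis-aligned
  steps are almost always rejected there, so two additional operators act
  on whole individuals: a joint scale move that multiplies $k_1, k_2$ by a
  common log-normal factor (dividing $SF$ by it), i.e. changes only the
  kinetic time scale, and Gaussian steps shaped by the covariance of the
  elite individuals.  A small block of offspring applies fine versions of
  these steps to the incumbent best each generation.
* **Termination.** Stop when the best fitness has not improved for 300
  generations — improvements smaller than a relative $10^{-10}$ are treated
  as "steady", so float-granularity refinements do not postpone the stop —
  or at a hard cap of 10 000 generations.
* **Ties and degeneracies.** The earliest-found best individual is
  retained; non-finite predictions (overflow at extreme parameters) receive
  an infinite objective rather than raising; negative observed
  concentrations (possible after blank correction) are accepted with a
  note.

`reference_fit()` is a deliberately independent check on the GA: an
exhaustive log-spaced grid over the same box followed by a derivative-free
Nelder–Mead polish on a logit-transformed (bound-respecting)
parametrisation.  It exists to validate `fit_model()` in the test suite,
not for routine use.

## Goodness of fit and model selection

With $n$ observations, $p$ fitted parameters ($p = 2$ for OC, $3$ for
OC-SF), residual sum of squares RSS and total sum of squares TSS:

$$R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}, \qquad
R^2_{adj} = 1 - \frac{n-1}{n-p}\,(1 - R^2),$$

$$\ln L = \tfrac12\left(-n\left(\ln 2\pi + 1 - \ln n +
\ln\textstyle\sum_i x_i^2\right)\right), \qquad
\mathrm{AIC} = 2p - 2\ln L, \qquad
\mathrm{AICc} = \mathrm{AIC} + \frac{2p(p+1)}{n-p-1},$$

$$w_i = \frac{\exp(-\Delta_i/2)}{\sum_k \exp(-\Delta_k/2)}, \qquad
\Delta_i = \mathrm{AICc}_i - \min_k \mathrm{AICc}_k.$$

Three conventions deserve emphasis because other software differs:

* The adjusted $R^2$ denominator is $n - p$, not the more common
  $n - p - 1$.
* $p$ counts only the kinetic parameters; the Gaussian error variance is
  profiled out in $\ln L$ and not counted.
* Akaike weights are always computed from the small-sample AICc (the
  $n/p < 40$ regime is the norm for these datasets), with the minimum
  subtracted before exponentiating for numerical stability.

A perfect fit makes $\ln L$ infinite; `compare_models()` then reports the
perfect-fit model as best with the whole weight (split among ties) and sets
a `degenerate` flag rather than emitting non-finite numbers.  Replicates
are never averaged before computing $R^2$; every point enters individually.

```{r selection}
adjusted_r_squared(0.9, n = 10, p = 2)
akaike_weights(c(0, 2))
```

## The scenario registry

`list_scenarios()` exposes 22 records: eight aquatic datasets (green algae,
water flea and zebrafish exposed to C60, TiO2, SiO2, graphene, graphene
oxide and Au nanomaterials), each under both models with the published
fitted constants and, where available, an independent literature fit for
comparison; plus the silver case studies (water flea exposed to Ag
nanoparticles for 48 h; earthworm exposed to Ag nanoparticles and to ionic
AgNO3 in soil).  Exposure durations and horizons are mostly not part of the
published records (they live in the underlying experimental studies), so
`scenario_series()` asks for them when a record does not carry one.  One
record (the dietary C60 water-flea row) carries a note about a
typographically ambiguous exposure concentration in the source layout; it
is stored with the parse consistent with the printed rate constants and is
excluded from exactness tests.  The registry is read-only at run time.

## Synthetic data and what the tests do (and do not) show

`generate_dataset()` evaluates a model on a sampling design and adds seeded
Gaussian noise — proportional (a fixed coefficient of variation, the
default, since concentration assays typically carry multiplicative error)
or additive.  The default design is ten uptake-phase and ten
elimination-phase points, evenly spaced, the layout of a typical
regulatory-style toxicokinetic study.  Negative simulated values are
clipped to zero by default (concentrations are physical) with the clip
count recorded; clipping can be disabled for statistically pure recovery
experiments.

The generator emulates replicate assay scatter around the analytic model.
It does **not** emulate medium transformation (dissolution, sedimentation,
aging of the exposure suspension), organism growth, time-correlated
drift, or model misspecification.  Passing recovery tests therefore
demonstrate that the estimator is correct and well-behaved *under the
model*, not that the OC or OC-SF model is adequate for any particular real
dataset.

Problem sizes used by the packaged studies: single-fit accuracy checks run
the full default configuration (population 1000, steady-fitness 300);
multi-fit simulation studies (parameter recovery across seeds, selection
consistency, nesting on randomised datasets) use a reduced configuration of
population 200 and steady-fitness 100, which on these 3-parameter problems
loses no material accuracy — noise, not search error, dominates there — and
keeps a full study at tens of fits.  The silver-uptake-like conditions
(48 h exposure, 48 h depuration, 12–20 points, 5 % proportional noise for
recovery and 2 % for selection studies) follow the calibration case study;
the selection study uses $SF = 0.2$, where the stored signal
($SF\,C_{exp}k_1 t_e$) is clearly expressed against 2 % noise.

## Known limitations

* No confidence intervals on the fitted constants; the GA provides point
  estimates only.
* Michaelis–Menten uptake, storage restricted to the elimination phase,
  growth dilution and particle-versus-ion dual bookkeeping are not
  implemented.
* Tissue-specific distribution is out of scope; the organism is one
  compartment.
* The GA is stochastic: different seeds can land on slightly different
  optima on flat likelihood surfaces (e.g. data that barely constrain
  $SF$); the seeded design makes any such outcome exactly reproducible.
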