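# biokin

One-compartment biokinetic modelling of contaminant — typically engineered
nanomaterial — uptake and elimination in soil and aquatic invertebrates, for
ecotoxicologists and environmental risk assessors who need kinetic rate
constants from time–concentration data without commercial statistics
software.

## The models and the statistics

In a two-phase study the organisms sit in a contaminated medium
(concentration `C_exp`) until the transfer time `t_e`, then in a clean
medium.  The plain **one-compartment (OC)** model is

    C(t) = C0 + C_exp * (k1/k2) * (1 - exp(-k2 t))                 0 <= t <= t_e
    C(t) = C0 + C_exp * (k1/k2) * (exp(-k2 (t - t_e)) - exp(-k2 t))     t > t_e

with uptake rate constant `k1` (L kg⁻¹ h⁻¹ aqueous, kg kg⁻¹ d⁻¹ soil) and
first-order elimination rate constant `k2`.  The **stored-fraction (OC-SF)**
model adds a dimensionless `SF ∈ [0, 1]`: a share `SF` of the influx is
sequestered in tissue (accruing as `SF·C_exp·k1·t` during exposure, frozen
at `t_e` thereafter) while the rest follows the OC dynamics scaled by
`(1 − SF)`.  At `SF = 0` the models coincide.

Rate constants are estimated by bounded real-coded **genetic-algorithm
nonlinear least squares** (population 1000, steady-fitness stop after 300
unimproved generations, `k2 ∈ [0.001, 100]`, single-threaded and seeded for
bit-exact reproducibility).  Candidate models are compared with adjusted
R² (denominator `n − p`), the small-sample **AICc**
(`AIC + 2p(p+1)/(n−p−1)`, with Gaussian profile log-likelihood and `p` = 2
or 3) and **Akaike weights** `w_i = exp(−Δ_i/2) / Σ exp(−Δ_k/2)`.

A registry of 22 published exposure scenarios (C60, TiO2, SiO2, graphene,
graphene oxide, Au, Ag nanomaterials and ionic AgNO3 in algae, water fleas,
zebrafish and earthworms) ships with the package, along with a seeded
synthetic-data generator and parameter-recovery harness.

## Worked example

Simulate a noisy silver-uptake-like experiment from the stored-fraction
model (`k1 = 0.426`, `k2 = 0.155`, `SF = 0.086`; 48 h exposure, 48 h
depuration, 5 % proportional noise), then fit both models and compare them:

```r
library(biokin)

sc    <- exposure_scenario(c_exposure = 1, t_e = 48, t_total = 96, dt = 1,
                           time_unit = "hour", medium_unit = "mg/L")
truth <- kinetic_params(k1 = 0.426, k2 = 0.155, sf = 0.086)
obs   <- generate_dataset("OC-SF", truth, sc,
                          noise = noise_spec("proportional", 0.05, seed = 42))

report <- fit_report(obs, sc, config = fit_config(population_size = 200,
                                                  steady_fitness_generations = 100,
                                                  seed = 1))
report
#> OC fit (n = 20): k1 = 0.200995, k2 = 0.0372445, SF = 0
#>   RSS = 4.94888 after 206 generations (steady-fitness stop)
#> OC-SF fit (n = 20): k1 = 0.393095, k2 = 0.131124, SF = 0.0885881
#>   RSS = 0.324425 after 884 generations (steady-fitness stop)
#>  model adj_r2   aicc delta    weight
#>     OC 0.7882  33.53  51.7 5.927e-12
#>  OC-SF 0.9853 -18.17   0.0 1.000e+00
#> best model: OC-SF
```

The OC-SF fit recovers the generating constants within the noise (its `k1`,
`k2`, `SF` sit near 0.426/0.155/0.086), its residual sum of squares is an
order of magnitude below the OC fit's, and the Akaike weight identifies the
stored-fraction model essentially with certainty.  Forcing the OC model on
these data inflates the apparent elimination half-life (`k2` drops to 0.037)
because the inert stored silver is misread as slow elimination — the reason
the stored-fraction extension exists.

Published fits are available for instant simulation:

```r
get_scenario("dmagna-graphene-aqueous-oc")$params   # k1 = 2766.4, k2 = 0.064
head(scenario_series("dmagna-agnp-ocsf", c_exposure = 1))
```

## Command line

A thin wrapper (`exec/biokin`) drives the same workflows from a shell:

```sh
biokin fit --data series.csv --model both --c-exposure 1 \
       --t-exposure 48 --t-total 96 --seed 1 --out results/
biokin simulate --scenario dmagna-graphene-aqueous-oc \
       --t-exposure 24 --t-total 48 --dt 1 --out curve.csv
biokin scenarios list
biokin recover --model oc --k1 0.196 --k2 0.033 --c-exposure 1 \
       --t-exposure 48 --t-total 96 --out recovery.csv
```

`fit` writes a self-contained JSON report (parameters, residuals, fit
statistics, Akaike comparison, echoed configuration and seed), per-model
predicted-curve CSVs and a plot-data CSV.  Exit codes distinguish usage
errors (2), input/parse errors (3) and numerical failures (4).

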