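# gliomaSynergy

An R package and analysis workflow for screening combinatorial drug synergy
in drug-resistant glioma *in silico*. It models a heterogeneous tumor as
four interacting cell populations, attaches saturating (Emax/Hill)
pharmacodynamic kill terms for temozolomide (TMZ) and three acridone
derivatives (AC2, AC7, AC26), and builds on that core: Bayesian parameter
inference, global sensitivity analysis, 100 × 100 dose-grid simulation,
Bliss-independence synergy surfaces, and the standard pharmacology
summaries (IC50, selectivity index, combination index, fold change).

It is written for modellers and pharmacologists who want to screen dose
combinations against a resistant tumor compartment before committing to
bench experiments.

## The model

Four populations: non-cancerous precursor cells $N$, undifferentiated
cancer cells $C$, drug-resistant cancer cells $C_R$ and drug-sensitive
cancer cells $C_S$. Precursors renew logistically and mutate into cancer
cells with probability $\rho$; cancer cells grow with Gompertz kinetics and
differentiate into the resistant/sensitive compartments with probabilities
$\gamma_R + \omega_S = 1$; the two compartments interconvert, with the
sensitive-to-resistant switch ($\tilde\gamma_R$) more probable than the
reverse ($\tilde\omega_S$):

$$\frac{dN}{dt} = \alpha_N N (1-\rho)\left(1 - \frac{N}{K}\right) - \delta_N N - \alpha_N N \rho$$

$$\frac{dC}{dt} = \alpha_N \rho N + \alpha_C C \log\frac{K}{C+\mu} - \gamma_R \alpha_C C - \omega_S \alpha_C C - \delta_C C$$

$$\frac{dC_R}{dt} = \gamma_R \alpha_C C + \tilde\gamma_R \alpha_{CS} C_S + \alpha_{CR} C_R \log\frac{K}{C_R+\mu} - \delta_R C_R - \tilde\omega_S \alpha_{CR} C_R$$

$$\frac{dC_S}{dt} = \tilde\omega_S \alpha_{CR} C_R + \omega_S \alpha_C C + \alpha_{CS} C_S \log\frac{K}{C_S+\mu} - \delta_S C_S - \tilde\gamma_R \alpha_{CS} C_S$$

Under treatment, $C_R$ and $C_S$ additionally lose cells at the rate

$$\frac{\varepsilon_{max} \, D^{\eta}}{IC_{50}^{\eta} + D^{\eta}}$$

per drug (TMZ dose $D_1$, acridone dose $D_2$), with per-drug,
per-compartment $\varepsilon_{max}$, Hill exponent $\eta$ and $IC_{50}$.
All 29 parameters live in `inst/extdata/default_params.yaml`; the IC50s
are the measured cell-line potencies and the kill capacities are calibrated
so the simulated 72-h monotherapy curves cross 50% growth at those doses.

Synergy is scored against Bliss independence,
$y_C = y_A + y_B - y_A y_B$ for fractional inhibitions, as the deviation of
the observed combined inhibition from that expectation (negative values are
what the source surfaces label synergy; see the methods vignette for the
sign-convention discussion).

## Worked example

```r
library(gliomaSynergy)
cfg <- read_params_config()

# untreated dynamics: the resistant compartment dominates at steady state
st <- steady_state(cfg$initial_state, cfg$growth)
round(unclass(st))
#>      N      C    C_R    C_S
#> 787862 296186 999006 832925

# 72-h relative growth of resistant cells under a TMZ + AC26 combination
relative_growth(cfg$growth, cfg$drug_effects$AC26, dose_pair(100, 0.5), "C_R")
#> [1] 59.97952

# Bliss synergy surface over the full 100 x 100 dose grid
m <- dose_response_matrix(cfg$growth, cfg$drug_effects$AC26,
                          dose_grid(acridone = "AC26"))
s <- synergy_surface(m)
mean(s[-1, -1])   # negative: net synergy over the grid interior
#> [1] -1.180916

# pharmacology summaries from measured dose-effect inputs
selectivity_index(482, 23.33)       # TMZ on the sensitive line
#> [1] 20.66
fold_change(190, 102.3)$ratio       # TMZ IC50 shift when paired with AC26
#> [1] 0.5384211
combination_index(36.3, 1.48, 190, 1.53)$interpretation
#> [1] "additive"
```

The steady state shows the resistant excess (`C_R* / C_S*` ≈ 1.20) that
motivates combination therapy; the negative mean synergy score says the
combination kills more of the resistant compartment than two independently
acting drugs would.

## The analysis workflow

The numbered scripts under `analysis/` run the study end to end, writing
tables under `results/`:

1. `01_growth_dynamics.R` — untreated dynamics and steady state
2. `02_fit_growth_parameters.R` — DRAM fit to synthetic 96-h growth curves
3. `03_dose_response_curves.R` — monotherapy curves and simulated IC50s
4. `04_combination_screen.R` — 100 × 100 dose grids and synergy surfaces
5. `05_sensitivity.R` — LHS-PRCC over all 29 parameters
6. `06_pharmacology_tables.R` — selectivity, fold-change and CI tables

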