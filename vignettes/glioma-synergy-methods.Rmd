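---
title: "Modelling combinatorial drug synergy in resistant glioma: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling combinatorial drug synergy in resistant glioma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomaSynergy)
```

## The model and its assumptions

gliomaSynergy models a growing tumor as four coupled ordinary differential
equations: non-cancerous precursor cells `N` that renew logistically and
mutate into cancer cells with probability `rho`; undifferentiated cancer
cells `C` that grow with Gompertz kinetics and differentiate into resistant
(`C_R`, probability `gamma_R`) and sensitive (`C_S`, probability
`omega_S = 1 - gamma_R`) compartments; and the two differentiated
compartments, which grow with their own Gompertz terms, die at their own
rates, and interconvert — the sensitive-to-resistant switch
(`gamma_R_tilde`) is more probable than the reverse (`omega_S_tilde`),
which is how the tumor drifts toward refractoriness.

The Gompertz growth contribution is written
`alpha * X * log(K / (X + mu))` with a single carrying capacity `K` shared
by all cancerous compartments and a small offset `mu` (default 1 cell) that
keeps the term finite at `X = 0`. The un-offset Gompertz law is singular at
zero abundance; the offset form behaves identically away from zero and lets
the model start from arbitrarily small seeds. We use the natural logarithm
throughout, the usual convention in growth kinetics. Whether the offset
should differ between compartments is not determined by anything in the
biology we represent, so one shared `mu` is used.

Drug action enters as saturating Emax/Hill loss terms on `C_R` and `C_S`
only: at dose `D` the compartment loses cells at rate
`emax * D^eta / (ic50^eta + D^eta)` per hour, with separate
(`emax`, `eta`, `ic50`) triplets per drug (TMZ; one acridone derivative)
and per compartment. Doses are constant over the whole integration window:
the response model has no clearance term, matching a fixed-concentration
bath as in a well-plate assay. The undifferentiated pool `C` and the
precursors `N` are untouched by either drug; this is a deliberate
simplification with visible consequences for synergy scoring (below).

## Parameters, units and defaults

All defaults live in `inst/extdata/default_params.yaml`, not in code.
Abundances are in cells (the model is scale-free up to `K`, whose default
of $10^6$ is nominal); rates are per hour; doses and IC50s in uM.

The 15 growth parameters were chosen once, against three requirements:
per-hour rates on the scale of glioma cell-line doubling times (20–40 h),
all four compartments at steady state within the 300-h simulation cap used
for equilibrium readouts, and a resistant compartment that settles above
the sensitive one (`C_R*/C_S*` ≈ 1.20 at the defaults), the configuration
that makes combination therapy interesting in the first place. The
transition asymmetry (`gamma_R_tilde = 0.1` vs `omega_S_tilde = 0.05`) and
the slightly favourable resistant birth/death rates produce that ordering.

The drug-effect IC50s are the measured cell-line potencies (TMZ: 190 uM
resistant / 23.33 uM sensitive; AC26: 0.76/0.9; AC2: 1.53/1.53; AC7:
1.05/5.67). `eta = 3` gives the curves a realistically steep shoulder, and
each `emax` was then calibrated — once, by one-dimensional root finding —
so that the simulated 72-h monotherapy curve of the targeted compartment
crosses 50% relative growth at its configured IC50. The calibrated kill
capacities land at 0.08–0.11 per hour. Reading the IC50 back off the
simulated curves returns the configured values within about 1–2%
(population dynamics reshape the curve slightly; exact equality is not
expected).

## Simulation

Integration uses deSolve's Dormand–Prince 4(5) adaptive Runge–Kutta
(`ode45`) with `rtol = atol = 1e-8` by default (`1e-6` inside the
dose-grid and sensitivity loops, where halving the tolerances moves
steady-state outputs by well under 0.1%). A compiled C copy of the
right-hand side backs the solver; the pure-R `growth_rhs()` /
`treated_rhs()` are the reference implementation and the test suite asserts
element-wise agreement between the two on random states.

Stiff kill terms can push a compartment a hair below zero numerically;
values are clipped to zero after integration and the clip count is kept as
an attribute. Steady state is declared at the first sampled hour where
`|dX/dt| / (X + mu)` drops below `1e-6` per hour for every compartment —
two to three orders of magnitude below the growth-rate scale — with a 300-h
cap and a warning (plus `converged = FALSE`) if the cap is hit.

Two readout horizons are used deliberately: a fixed 72-h horizon for
dose-response work, matching the 72-h drug exposure of the SRB viability
assay the curves emulate, and the steady-state horizon for equilibrium
questions. Both are exposed everywhere a readout is taken.

## Synthetic data

`generate_growth_data()` simulates the drug-free model over 0–96 h
(13 samples at 8-h spacing by default) and adds i.i.d. Gaussian noise,
truncated at zero, to the observed compartments — by default `C`, `C_R`
and `C_S`, the three a growth-curve experiment would track, with noise SD
at 5% of each compartment's trajectory mean. It emulates the shape and
error scale of SRB growth kinetics; it does not emulate absorbance units,
plate effects, or correlated errors, so parameter-recovery results say the
machinery works on well-specified data, not that real cell-line data are
this kind. `generate_dose_response_data()` produces Hill-shaped viability
readouts with percent-scale Gaussian noise for round-trip tests of the
IC50 interpolator.

## Inference

The sampler is a self-contained delayed-rejection adaptive-Metropolis
(DRAM) implementation: a Gaussian random walk whose covariance is adapted
from the chain history (scaled by `2.38^2/d` with a `1e-10` diagonal
jitter, updated every 100 iterations after iteration 1000), plus one
delayed-rejection stage that retries each first-stage rejection from a
5-fold-shrunk proposal with the proper second-stage acceptance ratio.
Correctness is pinned by tests against analytic targets: mean and
covariance of a correlated 2-D Gaussian, and a Kolmogorov–Smirnov check of
the non-adaptive sampler against a 1-D Gaussian (on a thinned chain, since
the KS null assumes independent draws).

The likelihood is Gaussian around the simulated trajectory with fixed,
user-supplied (or dataset-recorded) noise SDs; priors are independent
normals with hard biological-feasibility bounds, by default centred on the
packaged values with 30% SD and 0.2×–5× bounds. Of the 15 growth
parameters, `K`, `mu` and `rho` are fixed by default and the growth/death
rates and switching probabilities are candidates for estimation; the
desk-scale configuration estimates five rates from one synthetic dataset
in 20,000 iterations (the full-scale 500,000-iteration run is a
configuration choice away). When `gamma_R` is estimated, `omega_S` is
derived as `1 - gamma_R` so the differentiation probabilities stay
normalised. Parameter-recovery tests use 20 replicate datasets and ask the
generating value to fall inside the central 95% interval for at least 90%
of parameter–replicate pairs; posterior predictive envelopes include the
observation noise, so they are envelopes for new observations rather than
for the latent trajectory.

## Sensitivity analysis

`run_sensitivity()` spans all 29 parameters: the 15 growth parameters and
the TMZ triplets at ±50% of their defaults, the acridone triplets over a
range covering all three derivatives (0.5× the minimum to 1.5× the maximum
value across AC2/AC7/AC26), and the two doses over the screening ranges
(TMZ 0–200 uM, acridone 0–6 uM). Latin hypercube sampling comes from the
lhs package; PRCC is computed by rank-transforming everything
(average-rank ties), partialling each parameter and the output on the
remaining parameters by linear regression on ranks, and correlating the
residuals, with p-values from a t statistic on `n - 2 - (k - 1)` degrees
of freedom. `gamma_R` and `omega_S` are sampled independently and
renormalised to sum to one inside the model evaluation, so both columns
stay full-rank in the regression. A point range (`lo == hi`) holds a
parameter fixed and drops it from the correlation — used, for instance, to
sever the drugs' causal path by pinning every `emax` at zero and checking
the doses go non-significant. Failed simulations are dropped with a
logged count; more than 10% is an error. Which parameters clear `p < 0.05`
depends on the ranges chosen, so the significant-parameter counts are
reported but not treated as reproducing any external tally.

## Synergy scoring and its sign convention

The combination screen evaluates relative growth on a 100 × 100 linear
dose grid including zero (TMZ 0–200 uM; acridone 0–2 uM for AC2, 0–6 uM
for AC7 and AC26 — ranges within the 250/100 uM toxicity limits). The
monotherapy margins of the matrix give the single-drug fractional
inhibitions `yA`, `yB`; Bliss independence expects combined inhibition
`yA + yB - yA*yB`; the synergy score is the observed percent inhibition
minus that expectation, in percentage points, and is exactly zero on the
zero-dose margins.

The sign convention deserves a paragraph, because two conventions coexist
in the literature and they flip the reading. The surfaces this package is
built to reproduce label **negative** scores as synergy, and that is the
convention kept here. On the inhibition scale a negative deviation
literally means *less* combined inhibition than independent action
predicts — and this model family produces it structurally. At the Gompertz
steady state the combined growth fraction is exactly the product of the
monotherapy growth fractions (kill rates add in the exponent of
`X* = K exp(-(delta + kill)/alpha)`), i.e. exact Bliss additivity; the
deviations come from regrowth compensation (Gompertz growth accelerates as
a compartment is depleted) and from replenishment of the killed
compartments by the drug-insensitive undifferentiated pool, both of which
can only push observed inhibition below the expectation. The mean interior
score is therefore negative for every drug pair at the defaults (about
−1.2 percentage points for TMZ + AC26 at the 72-h horizon). Users
comparing against tools that report Bliss *excess* inhibition as positive
synergy should negate the scores.

## Pharmacology summaries

IC50 extraction interpolates linearly in log dose between the two
observations bracketing 50% growth, excluding the zero dose from the log
axis, and reports the maximum inhibition reached when a curve never
crosses 50%. The selectivity index is `CC50(Vero) / IC50(cancer line)`,
reported to two decimals. Fold change is `final / initial` IC50 with the
percent change reported as a magnitude. The combination index uses the
Chou–Talalay non-exclusive form without the interaction term,
`d1/IC50_1 + d2/IC50_2`, because the interpretation bands (< 0.8
synergism, 0.8–1.2 additive, > 1.2 antagonism) are standard but the
formula behind the reference experimental values is uncited; experimentally
measured CI values are consequently not targets this package tries to
reproduce.

## Problem sizes

The shipped configuration uses desk-scale sizes chosen to keep the full
study reproducible in minutes: 20,000 MCMC iterations per fit (with
500,000 available via configuration), 20 replicate datasets for the
recovery study, 500 Latin hypercube samples for the sensitivity tables
(200–400 in the tests), and the full 100 × 100 grid for the combination
screen.

## Known limitations

The model is deterministic and spatially unstructured: no angiogenesis,
immune compartments, micro-environment, or stochastic birth–death
fluctuations, and no pharmacokinetics (doses do not decay). The drugs act
only on the differentiated compartments, which is what limits the
attainable kill at high doses and shapes the synergy surfaces. The default
parameter set is a documented, internally consistent choice — not a fit to
any particular cell line — so quantitative outputs transfer to real systems
only after refitting `GrowthParams` and the drug triplets to data from
those systems.
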