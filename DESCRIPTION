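Package: gliomaSynergy
Title: Heterogeneous Tumor-Growth Modelling and Drug-Synergy Screening for
    Resistant Glioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation model of a heterogeneous glioma
    consisting of non-cancerous precursor, undifferentiated cancer,
    drug-resistant and drug-sensitive cell populations, with Emax/Hill
    pharmacodynamic kill terms for temozolomide and acridone derivatives.
    Provides adaptive Runge-Kutta simulation and steady-state detection,
    Bayesian parameter inference by a delayed-rejection adaptive-Metropolis
    (DRAM) sampler, global sensitivity analysis by Latin hypercube sampling
    with partial rank correlation coefficients, dose-grid simulation,
    Bliss-independence synergy surfaces, and pharmacology summaries (IC50
    extraction, selectivity index, combination index, fold change).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
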