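#!/usr/bin/env Rscript
# Monotherapy dose-response simulation: 72-h relative-growth curves for TMZ
# and the three acridone derivatives on the resistant and sensitive
# compartments, with the IC50 read back off each simulated curve.  Finding:
# the simulated IC50s track the measured cell-line potencies used to
# parameterise the kill terms (self-consistency of the calibration).

suppressPackageStartupMessages(library(gliomaSynergy))
dir.create("results", showWarnings = FALSE)

cfg <- read_params_config()
p <- cfg$growth
init <- cfg$initial_state

curve <- function(dp, compartment, drug, d_max, n = 60) {
  doses <- seq(0, d_max, length.out = n)
  g <- vapply(doses, function(d) {
    dd <- if (drug == "TMZ") dose_pair(d, 0) else dose_pair(0, d)
    relative_growth(p, dp, dd, compartment, "fixed", initial = init,
                    rtol = 1e-6, atol = 1e-6)
  }, numeric(1))
  data.frame(drug = drug, compartment = compartment,
             dose_uM = doses, relative_growth_pct = g)
}

cases <- rbind(
  data.frame(drug = "TMZ", label = "AC26", comp = c("C_R", "C_S"),
             d_max = c(250, 60), configured = c(190, 23.33)),
  data.frame(drug = "AC26", label = "AC26", comp = c("C_R", "C_S"),
             d_max = c(6, 6), configured = c(0.76, 0.9)),
  data.frame(drug = "AC2", label = "AC2", comp = c("C_R", "C_S"),
             d_max = c(6, 6), configured = c(1.53, 1.53)),
  data.frame(drug = "AC7", label = "AC7", comp = c("C_R", "C_S"),
             d_max = c(6, 20), configured = c(1.05, 5.67)))

all_curves <- list()
cat(sprintf("%-5s %-4s %10s %10s\n", "drug", "cell", "sim IC50", "configured"))
for (i in seq_len(nrow(cases))) {
  cc <- curve(cfg$drug_effects[[cases$label[i]]], cases$comp[i],
              cases$drug[i], cases$d_max[i])
  all_curves[[i]] <- cc
  ic <- ic50_from_curve(cc$dose_uM, cc$relative_growth_pct)
  cat(sprintf("%-5s %-4s %10.3f %10.3f\n", cases$drug[i], cases$comp[i],
              ic, cases$configured[i]))
}
write.csv(do.call(rbind, all_curves), "results/03_dose_response_curves.csv",
          row.names = FALSE)
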