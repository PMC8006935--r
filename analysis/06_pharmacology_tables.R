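#!/usr/bin/env Rscript
# Pharmacology summary tables from the measured dose-effect inputs:
# selectivity indices (CC50 on Vero cells over IC50 on each glioma line),
# IC50 fold changes of each drug in combination, and combination indices
# with their interpretation bands.

suppressPackageStartupMessages(library(gliomaSynergy))
dir.create("results", showWarnings = FALSE)

# measured CC50 (Vero) and IC50s (uM): sensitive line U-87, resistant T-98
dose_effect <- data.frame(
  drug = c("TMZ", "AC26", "AC2", "AC7"),
  cc50_vero = c(482, 66.08, 56.21, 48.17),
  ic50_u87 = c(23.33, 0.9, 1.53, 5.67),
  ic50_t98 = c(190, 0.76, 1.53, 1.05))
dose_effect$si_u87 <- mapply(selectivity_index, dose_effect$cc50_vero,
                             dose_effect$ic50_u87)
dose_effect$si_t98 <- mapply(selectivity_index, dose_effect$cc50_vero,
                             dose_effect$ic50_t98)
write.csv(dose_effect, "results/06_selectivity_index.csv", row.names = FALSE)
cat("selectivity indices:\n")
print(dose_effect, row.names = FALSE)

# measured single-agent vs in-combination IC50s on the resistant line (uM)
fc_in <- data.frame(
  pair = c("TMZ+AC26", "AC26+TMZ", "TMZ+AC7", "AC7+TMZ", "TMZ+AC2", "AC2+TMZ"),
  initial = c(190, 0.76, 190, 1.05, 190, 1.53),
  final = c(102.3, 0.67, 46.2, 0.96, 36.3, 1.48))
fc <- do.call(rbind, lapply(seq_len(nrow(fc_in)), function(i) {
  f <- fold_change(fc_in$initial[i], fc_in$final[i])
  data.frame(fc_in[i, ], fold_change = round(f$ratio, 2),
             pct_fold_change = round(f$percent, 2))
}))
write.csv(fc, "results/06_fold_change.csv", row.names = FALSE)
cat("\nfold changes:\n")
print(fc, row.names = FALSE)

# combination index of each pair at the in-combination IC50 doses
ci <- do.call(rbind, lapply(c("AC26", "AC7", "AC2"), function(ac) {
  i_t <- fc_in$pair == paste0("TMZ+", ac)
  i_a <- fc_in$pair == paste0(ac, "+TMZ")
  r <- combination_index(fc_in$final[i_t], fc_in$final[i_a],
                         fc_in$initial[i_t], fc_in$initial[i_a])
  data.frame(pair = paste0("TMZ+", ac), ci = round(r$ci, 2),
             interpretation = r$interpretation)
}))
write.csv(ci, "results/06_combination_index.csv", row.names = FALSE)
cat("\ncombination indices at the in-combination IC50 doses:\n")
print(ci, row.names = FALSE)
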