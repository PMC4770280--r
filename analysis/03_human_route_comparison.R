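#!/usr/bin/env Rscript
# Inter-species / inter-route extrapolation: 8.5e8 MSCs to a 70 kg human,
# intravenous vs intra-hepatic arterial, with the mouse-fitted cell
# parameters held fixed.

suppressPackageStartupMessages(library(mscpbk))
dir.create("results", showWarnings = FALSE)

human <- load_species_physiology("human")
table1 <- load_kinetic_params("table1")
dose <- 8.5e8
grid <- seq(0, 24, by = 0.05)

iv <- simulate_pbk(human, table1, dose_event("intravenous", dose), grid)
iha <- simulate_pbk(human, table1,
                    dose_event("intra_hepatic_arterial", dose), grid)

prof <- data.frame(
  time_h = grid,
  liver_iv_cells = amount_in_organ(iv, "liver", grid),
  liver_iha_cells = amount_in_organ(iha, "liver", grid))
write.csv(prof, "results/human_route_liver_profiles.csv", row.names = FALSE)

r24 <- prof$liver_iha_cells[grid == 24] / prof$liver_iv_cells[grid == 24]
cat(sprintf("Liver amount at 24 h: IV %.3g cells, IHA %.3g cells\n",
            prof$liver_iv_cells[grid == 24], prof$liver_iha_cells[grid == 24]))
cat(sprintf("Intra-hepatic arterial delivery gives a %.2f-fold higher\n",
            r24))
cat("24-h liver amount than IV at the same dose: dosing into the hepatic\n",
    "vascular bed bypasses the pulmonary first-pass entrapment.\n", sep = "")
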