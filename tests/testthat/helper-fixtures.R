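# Shared fixtures: bundled physiologies and the fitted mouse parameter set.
# Loaded once per test run.

mouse_phys <- load_species_physiology("mouse")
human_phys <- load_species_physiology("human")
table1 <- load_kinetic_params("table1")

iv_mouse <- dose_event("intravenous", 5e5)

# coarse default grid for tests that only need trajectory shape
grid24 <- seq(0, 24, by = 0.1)

sim_mouse_iv <- simulate_pbk(mouse_phys, table1, iv_mouse, grid24)

# independent total-cell accounting straight from the physiology tables,
# bypassing mass_weights()/total_cell_balance()
manual_total_cells <- function(sim) {
  phys <- sim$physiology
  org <- phys$organs[match(PBK_ORGANS, phys$organs$name), ]
  s <- sim$states
  s[, "C_arterial"] * phys$arterial_blood_volume +
    s[, "C_venous"] * phys$venous_blood_volume +
    as.numeric(s[, paste0("C_", PBK_ORGANS)] %*% org$vascular_volume) +
    rowSums(s[, paste0("A_", PBK_ORGANS)]) +
    s[, "D_cum"]
}

# lung parameter block, the most identifiable organ under IV dosing
lung_block <- c("lung.partition", "lung.k_arrest", "lung.k_release",
                "lung.k_depletion")
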