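# mscpbk

Whole-body physiologically based kinetic (PBK) modelling of intravascularly
administered mesenchymal stem cells (MSCs).

Systemically infused MSCs are large (~20 µm) cells that are entrapped in the
first capillary bed they meet — for an intravenous dose, the lung — and only
a fraction ever reaches the liver, heart or other target organs alive. For
anyone designing cell-therapy dosing regimens, the questions are
quantitative: how many cells are in each organ at each time, how many are
still alive at 24 h, and how much does the administration route change
delivery to the target organ? `mscpbk` answers these with a compact
compartmental model that is cheap enough to calibrate, perturb and
extrapolate across species.

## The model

The body is divided into eight compartments — arterial blood, venous blood,
lung, liver, spleen, kidney, heart and the rest of the body — connected by
the systemic circulation. The lung sits in series between the venous and
arterial pools and carries total cardiac output; the other organs perfuse in
parallel off the arterial pool; the spleen's venous outflow drains into the
liver (portal link). Cells in an organ's vascular space (concentration
`C_V_t`, volume `V_V_t`, inflow `Q_t`) leave in venous blood at the
partition-limited concentration `C_V_t / P_t` and exchange with an arrested
extravascular pool `A_E_t` by first-order arrest and release; arrested cells
are depleted irreversibly. For each organ `t`:

```
V_V_t dC_V_t/dt = Q_t C_in − (Q_t/P_t) C_V_t − k_arrest,t C_V_t V_V_t + k_release,t A_E_t
     dA_E_t/dt = k_arrest,t C_V_t V_V_t − (k_release,t + k_depletion,t) A_E_t
```

The central arterial and venous pools additionally lose cells at a blood
depletion rate constant, and every depletion flux accumulates in a ledger
`D_cum`, so total live cells + `D_cum` equals the administered dose at all
times (the suite checks this to < 1e−6 relative). The system is linear, so
outputs scale exactly with dose. The packaged fixture `"table1"` holds the
cell-specific parameter set fitted against a mouse flow-cytometry
biodistribution experiment (5 × 10⁵ GFP-MSCs IV; terminal sampling at
5 min–20 h, n = 5); bundled mouse/rat/human physiologies are transcribed
from the standard reference compilations.

On top of the simulator the package provides:

* **dosing routes** — intravenous and intra-hepatic arterial boluses;
* **calibration** — bounded Levenberg–Marquardt least squares on
  log10 concentrations with per-parameter fixed/free masks (e.g.
  disease-specific refits of one organ's block);
* **sensitivity** — relative sensitivity coefficients
  `RSC = (ΔC/C)/(ΔP/P)` by +0.1% forward perturbation, with the
  conventional `|RSC| > 0.5` high-sensitivity classification;
* **evaluation** — cells/kg normalisation, MPE (bias) and MAPE (precision)
  with 95% t-intervals, log-scale R²;
* **synthetic data** — a generator reproducing the mouse experiment's
  design (6 times × 6 compartments × n = 5, lognormal multiplicative
  noise) for parameter-recovery studies.

## Worked example

```r
library(mscpbk)

mouse  <- load_species_physiology("mouse")
table1 <- load_kinetic_params("table1")
sim <- simulate_pbk(mouse, table1, dose_event("intravenous", 5e5),
                    time_grid = seq(0, 24, by = 0.05))
survival_fraction(sim, 24)
#> [1] 0.2323274
amount_in_organ(sim, "lung", 24) / 5e5
#> [1] 0.1441719
```

About 23% of the dose is still alive at 24 h, and the lung is the dominant
depot (14% of the dose), with the liver next (7%). Route comparison in a
70 kg human at the clinical dose:

```r
human <- load_species_physiology("human")
g <- seq(0, 24, by = 0.05)
iv  <- simulate_pbk(human, table1, dose_event("intravenous", 8.5e8), g)
iha <- simulate_pbk(human, table1, dose_event("intra_hepatic_arterial", 8.5e8), g)
amount_in_organ(iha, "liver", 24) / amount_in_organ(iv, "liver", 24)
#> [1] 3.486457
```

Dosing into the hepatic vascular bed bypasses pulmonary entrapment and
raises 24-h liver delivery ~3.5-fold.

The numbered scripts under `analysis/` run the full workflows (mouse
simulation, sensitivity screen, human route comparison, parameter
recovery) and write their tables under `results/`.

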