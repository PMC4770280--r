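---
title: "A physiologically based kinetic model of circulating MSCs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A physiologically based kinetic model of circulating MSCs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscpbk)
```

## The model and its assumptions

`mscpbk` treats systemically administered mesenchymal stem cells (MSCs) as
inert, independently acting particles transported by blood flow. The body
is reduced to eight compartments — arterial blood, venous blood, lung,
liver, spleen, kidney, heart and a residual "rest of body" — linked by the
systemic circulation. Two processes govern the kinetics:

1. **Transport**: flow-limited delivery to each organ's vascular bed. The
   lung is in series between the venous and arterial pools and receives
   total cardiac output, which is what produces the strong first-pass
   entrapment of an intravenous dose. All other organs perfuse in parallel
   from the arterial pool. The spleen's venous outflow drains into the
   liver, standing in for the splanchnic/portal route, so total hepatic
   outflow is the hepatic arterial inflow plus the splenic flow.
2. **Vascular interaction**: within each organ, cells in the vascular space
   either leave with venous blood at the partition-limited concentration
   `C_V/P` or are arrested (entrapment in narrow vessels, endothelial
   adhesion) at first-order rate `k_arrest`; arrested cells are released
   back at `k_release` or eliminated at `k_depletion`. The circulating
   arterial and venous pools have their own depletion constant. Every
   depletion flux is routed to a single cumulative sink `D_cum`; no
   urine/feces split is attempted, because the data being modelled track
   only the disappearance of live cells.

Deliberately excluded (their time scales are long compared with the
24–72 h horizon, or they require data the model is not built on):
extravasation and tissue integration, proliferation and differentiation,
cell aggregation, flow redistribution, and any deformability submodel.

Two structural points were genuinely open and were resolved as follows.
Organ depletion acts on the **arrested pool only**, not on the organ
vascular pool: entrapped cells are the ones observed fragmenting, and the
circulating pools already carry their own depletion constant. That blood
depletion constant is applied to **both** the arterial and venous pools;
there is no physiological reason to single out one side of the circulation.
Both choices are isolated in `build_rate_matrix()` if a user wants to
explore the alternatives.

Because every process is first order, the state evolves as
`d(state)/dt = A state` with a constant 15 × 15 matrix (2 blood pools +
6 vascular concentrations + 6 arrested amounts + the depletion ledger).
Linearity gives two free invariants the test suite leans on: outputs scale
exactly with dose, and the columns of `A` are balanced so that total live
cells plus `D_cum` is conserved exactly.

## Physiological parameters

Bundled mouse, rat and human physiologies live in
`inst/extdata/physiology/*.yaml` as editable, per-value-commented files
(units fixed: kg, L, L/h). Values are transcribed from the standard
reference compilations of physiological parameters (fractional organ
weights, fractional blood flows, total blood volumes). Three conventions
deserve a note:

* **Liver inflow.** The compilations report *total* hepatic blood flow
  (arterial + portal). Since this reduced topology has no gut compartment,
  the liver's arterial-side inflow is stored as total hepatic flow minus
  the splenic flow that arrives via the portal link — the standard
  convention for reduced PBK models. Mouse 16.1%, rat 17.4% and human
  22.7% of cardiac output as totals.
* **Vascular volumes.** `V_V_t` is a required coefficient of the vascular
  mass balances but is rarely printed alongside organ weights; the bundled
  values use residual-blood fractions of organ volume from the same
  compilations (e.g. lung 0.50 in rodents, liver 0.31, rest of body 0.04).
* **Rest of body.** Receives the residual cardiac output and the residual
  volume (body weight minus blood pools minus named organs, at 1 kg/L), so
  the circulatory loop and the mass budget close by construction. The
  central arterial and venous pools are set to 25% and 50% of total blood
  volume, the remainder residing in organ vascular beds.

`validate_species_physiology()` enforces positivity, `V_V < V_total`,
`Q_lung = CO`, closure of the systemic flows to within 1%, and the volume
budget; `scale_physiology()` provides crude allometric rescaling (volumes
proportional to body weight, flows with exponent 0.75 by default).

## Cell-specific parameters

The fixture `"table1"` (`inst/extdata/kinetics/table1.csv`) carries the
fitted mouse parameter set: per organ a partition coefficient `P`
(unitless, 3.1–1633) and arrest/release/depletion rate constants (1/h,
0.002–5.4), plus the blood depletion constant 0.636 1/h. The spread of `P`
and the rates is what makes the system moderately stiff. The same
parameters are reused unchanged for rat and human predictions — the
cross-species assumption under test in the original study.
`generate_disease_variant()` rescales one organ's block (arrest, depletion,
partition multipliers) to emulate disease states such as an infarcted heart
(more arrest, less depletion) or a cirrhotic liver (more partition and
arrest).

## Dosing

Both routes are instantaneous boluses: a tail-vein push or catheter
injection is fast relative to the earliest (5 min) observation. IV adds
`dose / V_venous` to the venous pool; intra-hepatic arterial dosing adds
`dose / V_V_liver` to the liver vascular concentration, the simplest
construction that reproduces the bypass of the pulmonary first pass
(whether the original simulations dosed an upstream arterial stream instead
is not recoverable from the text; the difference is a few minutes of
transit). Dose application conserves the cell count identically, and
multiple events are supported as state jumps between integration segments.

## Numerics

The default integrator is `deSolve::lsoda` with the constant analytic
Jacobian, relative tolerance 1e−8 and absolute tolerance 1e−6 cells/L.
A fixed-step classical Runge–Kutta mode (`solver = "rk4"`, step 1e−4 h —
inside the stability bound set by the fastest vascular turnover,
`Q/V ≈ 9200`/h in the mouse lung) serves as an independent numerical
check; the suite requires agreement within 0.1% on every compartment over
24 h. Conservation is checked to 1e−6 relative on every trajectory, and
trajectories must not undershoot zero by more than solver noise. Output at
a dose time reports the post-dose state.

## Calibration

The loss is unweighted least squares on `log10(concentration + 1 cells/kg)`
— concentrations span about four orders of magnitude, and profiles are
plotted and judged on a log scale; the +1 offset only regularises exact
zeros and is negligible at data magnitudes (≥ 1e4 cells/kg). Optimisation
uses bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on log10-parameters
with default bounds bracketing the fitted mouse values by at least an order
of magnitude (`P ∈ [0.1, 1e4]`, rates `∈ [1e−4, 1e2]` 1/h), plus seeded
multi-start (default 5) as a stand-in for manual restarting. Observed
`"blood"` values are compared to the venous pool (terminal sampling is
predominantly venous).

With 25 parameters against a 6-compartment × 6-time design the full
problem is not identifiable; the recovery experiments therefore free one
organ's block at a time (the lung block in the shipped tests, being the
best-informed under IV dosing). `goodness_of_fit()` reports the R² of the
regression of predicted on observed, log10 scale by default.

## Sensitivity analysis

`relative_sensitivity()` implements the normalised local coefficient
`RSC = [(C' − C)/C]/(ΔP/P)` with a forward +0.1% perturbation (the
published convention); a central-difference mode exists for verification
and agrees within 1% in the tests. The default evaluation time is 24 h
post-injection, when circulating cell numbers have reached a relatively
steady state, and the default sweep covers only the 25 cell-specific
parameters — physiological parameters are measured quantities, not fitted
ones, and perturbing them is a different (out-of-scope) exercise.
`parameter = "dose"` is accepted as a known-linear control whose RSC must
be exactly 1, which the suite uses as a harness check. `|RSC| > 0.5` flags
high sensitivity.

## Evaluation statistics

`prediction_errors()` uses the standard percentage forms relative to the
observation: `MPE = (100/N) Σ (M_pred − M_obs)/M_obs` (bias) and
`MAPE = (100/N) Σ |M_pred − M_obs|/M_obs` (precision), each with a
t-interval `mean ± t_{0.975, N−1}·SE` over the per-pair errors — with the
small N typical of biodistribution studies a normal interval would be
anticonservative. `MAPE ≥ |MPE|` always, with equality exactly when all
errors share a sign. Concentrations are compared on the cells-per-kg scale
(`normalize_to_cells_per_kg()`, density 1 kg/L).

## Synthetic data

`generate_dataset()` emulates the design of the calibrating mouse
experiment: terminal sampling at 5 min, 15 min, 1, 3, 10 and 20 h; measured
compartments blood, lung, liver, spleen, kidney, heart; n = 5 animals per
point. Noise is multiplicative lognormal with unit-mean factors —
flow-cytometry counts of rare events have right-skewed, scale-proportional
error — at a default CV of 0.25. The true replicate-level dispersion of
such experiments is not recoverable from published mean ± sd figures, so
the CV is a convention, exposed in `noise_model()`. The generator does not
simulate gating, fluorescence brightness or dissociation losses; passing
recovery tests therefore demonstrates identifiability under the assumed
noise law, not robustness to real cytometry artefacts.

Under the default design, the end-to-end experiment (generate with the
table-1 truth, refit the lung block from a 1.5×-perturbed start) recovers
noiseless data to well under 5% per parameter and noisy data (CV 0.25,
n = 5) to within 25% in at least 90% of 20 seeded replicates — the
tolerance reflecting the sparse 6-point design.

## Problem sizes and runtimes

The shipped tests and the acceptance script use 24-h simulations on grids
of 100–500 points (milliseconds each with the stiff solver), one 240 000
step fixed-step verification run, a 200-replicate Monte-Carlo check of the
generator's unbiasedness, and 20 replicate fits of the 4-parameter lung
block (a few seconds each). These sizes were chosen so the full suite
exercises every claim in minutes while remaining statistically meaningful.

## Known limitations

* The mass balances are reconstructed from a prose description and a
  circulatory schematic rather than a printed equation set. The main
  ambiguity (whether organ vascular pools are also depleted directly) is
  noted above and excluded.
* Physiological values are transcriptions from reference compilations;
  vascular-volume fractions in particular vary between sources, and
  headline quantities (24-h survival, route ratio, borderline sensitivity
  classifications) shift by a few points across plausible transcriptions.
* The model is linear: saturation of entrapment sites at high doses, cell
  aggregation, and dose-dependent flow changes are outside its scope.
* Calibration assumes per-time-point means; no animal-level mixed-effects
  structure is modelled.
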