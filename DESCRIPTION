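Package: mscpbk
Title: Physiologically Based Kinetic Modelling of Administered Mesenchymal Stem Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Whole-body compartmental kinetic modelling of intravascularly
    administered mesenchymal stem cells (MSCs). Implements an eight-compartment
    physiologically based kinetic (PBK) model in which organs are connected by
    the systemic blood circulation and cells undergo first-order arrest,
    release and depletion in each organ's vascular bed. Provides bundled
    mouse, rat and human physiologies, simulation of intravenous and
    intra-hepatic arterial dosing, bounded least-squares calibration of
    cell-specific parameters from biodistribution time courses, local
    sensitivity analysis via relative sensitivity coefficients, prediction
    error statistics (MPE/MAPE with confidence intervals), and a synthetic
    biodistribution data generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
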