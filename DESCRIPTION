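Package: coroflow
Title: One-Dimensional Coronary Haemodynamics and Wave-Free Pressure Indices
Version: 1.0.0
Authors@R:
    person("Coroflow", "Developers", email = "maintainers@coroflow.dev",
           role = c("aut", "cre"))
Description: A reduced-order framework for computing pressure-derived indices
    of coronary stenosis severity on arterial tree geometries. Implements a
    one-dimensional pressure-flow formulation of pulse-wave propagation with a
    viscoelastic tube law, coronary terminal beds with intramyocardial
    (ventricular) external pressure, a simplified closed-loop heart model that
    generates resting and hyperaemic inflow waveforms, computation of the
    fractional flow reserve (cFFR) and instantaneous wave-free ratio (ciFR),
    forward/backward wave separation, and the statistical layer (polynomial
    index relations, Bland-Altman, ROC/Youden) used to estimate diagnostic
    thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
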