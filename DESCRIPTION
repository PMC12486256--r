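Package: mpcest
Title: Multiparametric CEST MRI Simulation and T2-Corrected Dynamic
    Glucose-Enhanced Quantification
Version: 0.1.0
Authors@R: person("MP-CEST", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative glucoCEST (glucose chemical exchange
    saturation transfer) MRI. Provides a multi-pool Bloch-McConnell
    Z-spectrum simulator with an analytical rotating-frame (R1rho)
    saturation model, voxel-wise mono-exponential T2 and
    saturation-weighted proton-density mapping of multi-echo image stacks,
    dynamic glucose-enhanced (DGE) time-course quantification at a single
    offset and via MTR asymmetry, and a two-step simulation-calibrated
    correction that removes T2-relaxation confounds (spillover and readout
    decay) from DGE signals. Includes a synthetic-data module emulating
    digital glucose phantoms and dynamic uptake experiments with coupled
    glucose/T2 time courses, plain NIfTI-1 image I/O with JSON sidecars,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
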