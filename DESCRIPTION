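Package: vibrafrag
Title: Cluster Models and Harmonic Vibrational Spectra for Molecular Crystals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds finite cluster models from periodic crystal structures --
    the isolated single molecule, the minimal hydrogen-bonded repeating unit,
    the central molecule extracted from the optimized unit, and the intercepted
    multi-molecular fragment with hydrogen link-atom capping -- and computes
    harmonic vibrational frequencies by mass-weighted Hessian diagonalization
    with rigid-body (Eckart) projection over a pluggable energy backend.
    Includes a subset CIF reader and supercell builder, periodic bond
    perception and molecule extraction, geometric hydrogen-bond detection,
    a harmonic toy force field with analytic gradients, a quasi-Newton
    geometry optimizer, empirical frequency scale factors, broadened IR
    spectrum synthesis, and MAE/RMSE scoring of calculated frequencies against
    experimental peak lists.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
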