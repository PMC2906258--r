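Package: xtalfit
Title: Crystallographic Model-to-Data Fit, Statistics and Likelihood-Weighted Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for assessing how well a macromolecular model explains
    reduced crystallographic observations. Reads PDB models (multi-model
    ensembles, anisotropic displacement parameters, TLS header records in the
    two common dialects) and reflection data in SHELX, CNS or plain-column
    text; computes structure factors by direct summation or FFT density
    sampling for X-ray or neutron scattering; fits a flat bulk-solvent model
    with anisotropic scaling; evaluates merohedral twin laws and twin
    fractions; resolves the total-versus-residual ADP convention for
    TLS-refined models; estimates Wilson B factors, detects reflection
    outliers, and audits the pathological model and data features commonly
    found in deposited structures. Produces sigma-A weighted map coefficients
    (2mFo-DFc and relatives), real-space map correlations per atom or residue,
    and a four-section plain-text report with a machine-readable JSON twin.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
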