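Package: flowbond
Title: Receptor-Ligand Bond Rupture Kinetics in Laminar Flow Chambers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of single and divalent receptor-ligand attachments
    rupturing under hydrodynamic force in a laminar flow chamber. Implements
    a time-strengthening dissociation law in which the off-rate of a newly
    formed bond decays as k(F,0)/(1 + a(F) t), fitting of its two parameters
    from censored arrest-duration survival curves, Bell-type exponential
    force regression and half-force extrapolation, the shear-to-force
    hydrodynamic mapping for a sphere tethered near a wall, corrections for
    nonspecific arrests and detection-window censoring, and a kinetic Monte
    Carlo simulator of dimer-mediated attachments with rebinding and force
    sharing. A synthetic flow-chamber data generator makes the full pipeline
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    yaml
Config/testthat/edition: 3
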