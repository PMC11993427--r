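Package: cardioflow
Title: Left-Ventricular Flow-Component Separation from 4D Flow MRI and
    FAIR-ASL Myocardial Blood Flow Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pathline-based separation of the left-ventricular end-diastolic
    blood pool into its four functional flow components (direct flow, retained
    inflow, delayed ejection flow, residual volume) with kinetic-energy
    accounting, computed from time-resolved three-directional velocity fields
    (4D flow MRI); and myocardial blood flow quantification from FAIR arterial
    spin labelling series via the single-TI Buxton model, with polar resampling,
    spatiotemporal filtering, segmental reporting, and decomposition of temporal
    noise into physiological and thermal components. Synthetic phantom
    generators with oracle-computable ground truth (uniform duct, solid-body
    rotation, contracting half-ellipsoid ventricle, FAIR-ASL forward model)
    stand in for patient scans and drive the validation suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
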