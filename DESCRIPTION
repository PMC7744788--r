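Package: acpfa
Title: Electro-Thermal Simulation and Outcome Metrics for AC Pulsed-Field Cardiac Ablation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for modelling AC-burst pulsed-field ablation (PFA) of the
    heart. Provides charge-balanced AC burst waveform synthesis with ECG-gated
    burst-train scheduling, voxelized catheter/tissue scenario builders
    (pulmonary vein ostium, atrial wall, interventricular septum), a
    quasi-static conduction solver with Joule heating, a bioheat transient
    integrator with convective blood cooling, irreversible-electroporation
    lesion-extent metrics (effective field radius, untreated gap, alignment
    sensitivity), exponential temperature-decay fitting, MRI-style
    segmentation volumetrics, and the accompanying electrophysiology
    statistics. Synthetic-data generators make every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
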