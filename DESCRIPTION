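Package: tacsdose
Title: Dose-Response Analysis of tACS Aftereffects from Electric-Field
    Models and MEG Source Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for explaining inter-individual
    variability of transcranial alternating current stimulation (tACS)
    aftereffects on alpha oscillations. Provides analytic layered-sphere
    volume conduction (tES injected-current potentials and electric fields,
    spherical-conductor MEG leadfields), a seeded synthetic MEG cohort
    generator with a configurable planted dose-response aftereffect,
    Hanning-window spectral analysis with individual alpha frequency
    detection, a DICS (dynamic imaging of coherent sources) beamformer with
    neural activity index normalization, cluster-based permutation
    statistics on source grids, and the dose-response statistical core:
    full-factorial regression of source-space alpha power changes on
    spatial precision, frequency precision and field strength, with
    all-subsets AIC model selection and leave-one-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    rlang,
    ggplot2,
    RNifti,
    signal
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    pracma,
    optparse
Config/testthat/edition: 3
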