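Package: megdecode
Title: Simulation and Time-Resolved Decoding of Body-Part Category
    Responses in MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates synthetic magnetoencephalography (MEG) epochs with
    category-specific evoked responses using a spherical-conductor dipole
    forward model, and analyses them with the standard evoked-field
    pipeline: zero-phase filtering, baseline correction, channel
    selection, artifact rejection, per-category evoked averaging and peak
    extraction, regularized minimum-norm source estimation with per-vertex
    ANOVA F-mapping, and time-resolved multivariate decoding of body-part
    categories (foot, hand, mouth) with linear support-vector classifiers,
    stratified cross-validation, and a random-class null scheme.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
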