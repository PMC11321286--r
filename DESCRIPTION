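Package: gascreenr
Title: AI-Assisted Prescreening for Geographic Atrophy Clinical Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing an imaging-based prescreening
    pipeline for geographic atrophy (GA) clinical trials. Quantifies GA lesion
    area from en-face retinal pigment epithelium (RPE) segmentation maps,
    locates the fovea from neurosensory retina thickness maps, classifies
    lesion location relative to the fovea, applies declarative trial
    eligibility criteria, performs keyword-based electronic health record
    search, and implements the stratified clinical-validation statistics
    (positive predictive value with bootstrap confidence intervals, weighted
    cohort-yield inference, intraclass correlation, Bland-Altman limits of
    agreement, and bootstrap group comparisons). A seeded synthetic-cohort
    generator with planted lesions of known area and location makes every
    stage testable without access-restricted hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
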