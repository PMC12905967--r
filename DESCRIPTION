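Package: fcTarget
Title: Connectivity-Guided TMS Target Localisation and Trial Outcome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Personalised transcranial magnetic stimulation (TMS) targeting from
    resting-state functional connectivity, together with the clinical outcome
    statistics of an open-label migraine rTMS trial design. Provides volumetric
    containers with NIfTI-1 input/output and MNI-mm coordinate handling, sphere
    and composite region-of-interest construction for the left dorsolateral
    prefrontal cortex (DLPFC), discrete-cosine high-pass filtering and Gaussian
    spatial smoothing of BOLD series, seedmap-weighted extraction of the
    pregenual cingulate (PGC) seed time series, voxelwise DLPFC-PGC connectivity
    mapping with top-percentile cluster-centroid target selection, electric-field
    summary indices, seeded phantom and clinical-cohort simulators, responder
    classification and repeated-measures outcome statistics, and ROC analysis of
    connectivity change as a treatment-response biomarker.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
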