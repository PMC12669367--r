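Package: tractgap
Title: Error Assessment for Tractography-Guided Electrode-to-Tract Distance
    Measurement in Deep Brain Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies three error sources that arise when probabilistic
    tractography is used to measure distances between deep brain stimulation
    (DBS) electrode contacts and subcortical fiber tracts: the choice of
    binarization threshold (expressed as a percentage of the robust intensity
    range of a streamline-count map), manual distance measurement restricted
    to the axial slice of a contact versus automated lookup in a 3D Euclidean
    distance map, and spatial normalization of landmark coordinates into a
    standard space.  Includes a synthetic phantom generator (tube-like tract
    probability maps with heavy-tailed count histograms, multi-contact
    electrode trajectories, a red-nucleus-like landmark, and imperfect
    normalization transforms) so the full pipeline is testable without
    patient data, an exact anisotropic Euclidean distance transform, and
    cohort-level error summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
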