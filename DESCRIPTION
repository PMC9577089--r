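Package: cbparc
Title: Connectivity-Based Parcellation and Cross-Species Connectivity
    Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Subdivides a cortical seed region by spectral clustering of
    probabilistic-tractography connectivity profiles, builds group-level
    maximum probability maps with a 26-neighbourhood tie-break, scores
    parcellation reproducibility by split-half resampling (Dice, Cramer's V,
    normalized mutual information, variation of information) with an
    optimal-cluster-number rule, and compares regional connectivity
    fingerprints within and across species by cosine similarity and
    Manhattan distance.  Includes a synthetic multi-subject cohort
    generator with planted, spatially contiguous clusters so that every
    stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
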