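Package: tomocad
Title: Detection of Microcalcification Clusters in Digital Breast
    Tomosynthesis Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A computer-aided detection (CADe) pipeline for clustered
    microcalcifications in reconstructed digital breast tomosynthesis (DBT)
    volumes.  Candidate microcalcifications are enhanced with a multiscale
    Hessian objectness filter and a slice-wise band-pass (SNR) filter, combined
    into a multiscale object-type response, segmented by 3D connected-component
    labeling, grouped into cluster candidates by a 5 mm association rule, and
    screened by a rule-based false-positive reduction cascade.  Detections are
    scored against ground-truth annotations with free-response ROC (FROC)
    analysis.  A synthetic phantom generator with known cluster ground truth
    makes every stage testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
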