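Package: crossmode
Title: Cross-Validated Canonical Covariation Between Striatal Receptor
    Availability and Cerebral Blood Flow, with Imaging Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking spatial patterns in one voxel domain
    (striatal dopamine D2/3 receptor availability from PET) to patterns in
    another (brain-wide cerebral blood flow from arterial spin labeling)
    via cross-validated canonical correlation analysis with permutation
    inference, including exchangeability-block permutation for repeated
    measures, variogram-matched spatial surrogate maps, within-subject
    pharmacological-challenge analyses, partial least squares regression
    linking covariation influence maps to spatial gene expression with
    bootstrap VIP ranking, and median-rank gene-set enrichment.  A
    synthetic-data module generates cohorts with planted ground truth so
    that every stage of the pipeline can be exercised and calibrated
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    fgsea
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse
Config/testthat/edition: 3
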