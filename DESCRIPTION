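Package: blockcpm
Title: Block-Wise Connectome-Based Prediction and Two-Group Behavioral PLS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing block-design task fMRI connectomes: block-wise
    Fisher-z functional connectivity and signed network-strength scoring against
    trinary edge masks, connectome-based predictive modelling (CPM) with
    leave-one-site-out cross-validation and consensus masks, hypergeometric
    edge-set overlap tests, computational lesioning of network masks by
    macroscale region with bootstrap group comparison, two-group behavioral
    partial least squares with permutation and bootstrap-ratio inference, and
    auxiliary statistics (dependent-correlation tests, weighted correlation,
    within-subject block tracking, recognition d-prime). Includes a synthetic
    multi-site study generator with planted ground truth for end-to-end
    validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
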