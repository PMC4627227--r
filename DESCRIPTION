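Package: foldcall
Title: Replicate-Free Differential Expression and Pathway Networks for
    Four-Condition RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for replicate-free four-condition RNA-seq
    designs (self-renewing vs senescent cells, with and without cytokine
    priming): ERCC spike-in quality control, beta-actin-anchored
    length-corrected normalization, replicate-free differential-expression
    calling with a conservative posterior generalized fold-change score,
    cross-condition classification and hierarchical clustering of condition
    profiles, hypergeometric gene-set over-representation with
    Benjamini-Hochberg control, and a weighted shared-gene pathway network.
    Includes a synthetic count-data generator with programmed ground truth
    for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
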