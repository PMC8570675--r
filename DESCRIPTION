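Package: mirpipe
Title: Plasma Small RNA-Seq miRNA Quantification and Biomarker Analysis
Version: 0.1.0
Authors@R:
    person("Plasma", "smallRNA", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for plasma small RNA sequencing studies:
    adapter trimming and read cleaning, collapsing to unique sequences,
    mismatch- and end-variation-tolerant annotation against miRNA precursor
    hairpins, novel-candidate classification by eleven secondary-structure
    criteria, median-of-ratios library-size normalization, raw p-value
    differential-expression screening, and circulating-biomarker statistics
    (ROC curves, univariate and gated multivariable linear models of pain
    interference). Includes a seeded synthetic-data generator so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
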