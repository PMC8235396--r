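Package: pgxforest
Title: Mining Pharmacogenomic Interactions with Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A statistical framework for mining drug-gene interactions from
    large cancer cell-line screens. Binary genomic alteration profiles
    (somatic mutations, deletions, amplifications) are reduced by a
    three-step, response-blind procedure (driver-gene filter, binary-variance
    filter, redundancy clustering), one random-forest regression per compound
    is fitted on dose-response AUCs, predictive performance is scored by the
    concordance correlation coefficient between observed responses and
    out-of-bag predictions, alteration influence is tested by per-tree
    out-of-bag permutation importance with normal z-tests and Bonferroni
    correction, and compound pairs with similar mean AUC but different top
    alterations are screened for statistical drug-gene interactions by
    two-way ANOVA on logit-transformed AUC. Includes a synthetic-study
    generator with planted effects so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
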