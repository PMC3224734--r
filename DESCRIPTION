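Package: cypmod
Title: Structure-Anchored Annotation Transfer for Cytochrome P450
    Monooxygenases
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds profile hidden Markov models from annotated
    structure-based seed alignments of cytochrome P450 monooxygenases
    (CYPs) and transfers structural annotations onto query protein
    sequences: the structurally conserved regions (SCRs) of the CYP fold,
    the substrate-specificity hotspot equivalent to phenylalanine 87 of
    CYP102A1 (P450 BM-3), and the lengths of the two reductase
    interaction sites (RIS1, the alphaJ/J' region; RIS2, the insertion
    between the meander loop and the Cys-pocket) with redox-class
    assignment.  Includes glocal Viterbi and forward scoring, an
    applicability gate for non-CYP folds, batch composition and
    length-distribution statistics, leave-one-out cross-validation of
    anchor-position prediction, and a synthetic seed/query generator with
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
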