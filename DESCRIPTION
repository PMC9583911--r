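Package: kmerprint
Title: Reference-Free Microbial DNA Fingerprints for Human Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers individual-specific microbial DNA fingerprints from
    multi-site, multi-timepoint skin shotgun metagenomes without any reference
    genome. Canonical 31-mers are counted per sample, logicalized, and scored
    as single-feature presence/absence predictors by the average of sensitivity
    and specificity (ASS); individual-specific k-mers recruit reads that are
    assembled into contigs with a built-in de Bruijn unitig assembler; one
    fingerprint contig per individual is selected by cross-validated AUC of its
    RPKM abundance and given a ROC-derived decision threshold; a Gini-index
    decision tree over fingerprint RPKM values identifies the donor of an
    unknown sample, with an unlabeled outcome for out-of-cohort donors. A
    synthetic cohort simulator with planted private variants provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
SystemRequirements: C++17
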