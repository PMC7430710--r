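Package: placmatch
Title: MHC Compatibility and Retained Fetal Membranes in Mare-Foal Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for testing whether major histocompatibility
    complex (MHC) similarity between a mare and its foal, assayed by nine
    MHC-linked microsatellites, is associated with retained fetal membranes
    (RFM). Provides multilocus microsatellite genotype I/O (CSV and GenePop),
    mare-foal compatibility classification (MC/FC/MFC/NC) per MHC class,
    Queller-Goodnight pairwise relatedness, pedigree-based kinship and
    inbreeding coefficients, locus quality control (Hardy-Weinberg exact
    tests, genotypic linkage-disequilibrium permutation tests, null-allele
    frequency estimation), logistic regression of RFM on compatibility with
    pseudo-R-squared summaries, exact binomial incidence intervals, and a
    seeded generator of study-like synthetic datasets (linked-locus trios,
    null alleles, configurable outcome model, pedigrees).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
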