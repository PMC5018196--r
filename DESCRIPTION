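Package: snvensemble
Title: Ensemble SNV Consensus Calling Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for the computation-defining stages of
    large-cohort ensemble single-nucleotide-variant (SNV) calling: fixed-size
    genome binning with flanking buffers for scatter-gather joint calling,
    k-of-n consensus filtering over multiple caller callsets, gold-standard
    evaluation (sensitivity, specificity, FDR, Ti/Tv, known-site overlap,
    genotype concordance, allele-count-stratified sensitivity), SNV-count
    based imputation window scheduling with overlap stitching, and a
    synthetic multi-caller cohort simulator with a closed-form
    Poisson-binomial oracle for expected consensus operating
    characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    yaml,
    vcfR,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
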