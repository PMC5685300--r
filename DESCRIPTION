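Package: plasmaFF
Title: Fetal DNA Fraction from Shallow-Depth Sequencing of Maternal Plasma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the fetal DNA fraction of a maternal plasma sample from
    shallow-depth whole-genome sequencing (around 0.03-fold coverage) by
    counting, at SNP sites where the mother is homozygous, the fraction of
    sequenced bases that carry a non-maternal allele, and converting that
    fraction to a fetal DNA percentage through a linear calibration model.
    Includes readers for maternal/fetal genotypes (VCF or TSV) and plasma
    alignments (SAM/BAM), the gold-standard fraction computed from known fetal
    genotypes, k-fold cross-validation, read and SNP downsampling, a sequencing
    depth by SNP-count accuracy grid, and a synthetic-data generator that
    emulates the assumed error model so the full pipeline is testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    optparse,
    Rsamtools,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
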