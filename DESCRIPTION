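Package: asebalance
Title: Allele-Specific Expression Analysis for Allelic-Discrimination qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for allele-specific expression (ASE) measured
    by dual-dye (FAM/VIC) allelic-discrimination quantitative PCR in
    heterozygous donors. Implements genomic-DNA-normalized delta-Ct
    statistics (nDCt), two-pass box-plot outlier filtering of replicate
    measurements, per-sample and pooled allelic-imbalance t-tests,
    conversion of nDCt values to risk-allele expression ratios,
    mixture-series sensitivity calibration, standard-curve relative
    quantification of total gene expression with genotype-group
    comparison by Mann-Whitney U test, and a noncentral-t power and
    sample-size calculator. A synthetic-data generator with configurable
    allelic ratio, dye bias, amplification efficiency and replicate noise
    stands in for instrument plate exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
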