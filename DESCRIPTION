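Package: chromRCA
Title: Reduced Chromatin Accessibility Regions, Methylation Sites, TADs and
    Hi-C Contacts: an Integrative Interval Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects regions of reduced chromatin accessibility (RCAs) by
    overlap subtraction of condition-specific ATAC-seq peak sets, annotates
    them against a gene model, classifies them into chromatin states by
    H3K4me3/H3K4me1 TPM ratios with CTCF/cohesin insulator sub-typing, pairs
    promoter RCAs with downregulated genes, tests RCA co-occurrence inside
    topologically associating domains (TADs) with an uncorrected chi-squared
    test, and mines significant Hi-C contact pairs for promoter-anchored
    (area-1) and distal (area-2) neighborhoods of intergenic RCAs and DNA
    hypermethylation sites. Ships a seeded synthetic-data generator that
    plants all of this structure with a ground-truth manifest, so every stage
    is verifiable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
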