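Package: autozyg
Title: Autozygosity Mapping and Recessive-Variant Prioritization with
    Voltage-Clamp Kinetics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for recessive Mendelian gene discovery in
    livestock-style pedigrees: gene-drop simulation of a founder-derived
    recessive allele, SNP-array homozygosity mapping (shared identical-by-state
    runs across cases plus a haplotype-window association scan), two-stage
    private-variant filtering of whole-genome callsets with codon-aware
    multi-nucleotide variant (MNV) consequence annotation, Hardy-Weinberg and
    segregation statistics, and single-exponential fitting of two-electrode
    voltage-clamp current traces with group comparison of activation time
    constants.  A synthetic-data generator with full ground-truth bookkeeping
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    vcfR,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
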