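Package: mitoqc
Title: Quality Control and Comparison of Circular Mitogenome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares draft and polished circular mitochondrial genome
    assemblies at base resolution: canonical rotation and strand
    normalization, anchor-based difference calling with left-normalized
    indels, parsing of PAF alignments with cs difference strings,
    consensus quality (QV) estimation, attribution of errors to
    homopolymer context, AT-content and coverage windowing with detection
    of technology-specific AT-rich segments, annotation completeness and
    premature stop codon checks, and circular gene-order breakpoint
    analysis. Ships a seeded simulator of gastropod-like mitogenomes with
    nanopore-style indel error and short-read coverage models so every
    stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
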