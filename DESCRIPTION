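Package: strdose
Title: Short Tandem Repeat Dosage Analysis of Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for using short tandem repeat (STR) copy-number dosage as a
    quantitative-trait marker in aquaculture and other pedigreed populations.
    Provides a perfect-repeat scanner with MISA-style thresholds and genome
    landscape statistics, parsing and quality filtering of HipSTR-dialect STR
    VCFs into relative-copy-number dosages, polymorphism information content
    and multiallelic Hardy-Weinberg tests, a VanRaden-style genomic
    relationship matrix generalised to multiallelic dosages, REML mixed
    linear model association scans with phenotypic variance explained,
    pedigree animal-model BLUP with adjusted phenotypes and dosage
    correlation filtering, FPKM-based two-group differential expression with
    STR-to-gene interval annotation, and a fully seeded synthetic cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
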