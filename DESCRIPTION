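Package: bstag
Title: Design and In Silico Validation of Bar-Coded Split Tags for
    Multiplexed Post-PCR Fluorescent Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing 16-nt bar-coded split tags (BStags) used for
    selective post-PCR fluorescent labeling of SSR, indel and SNP genotyping
    assays. Provides a calibrated nearest-neighbor melting-temperature engine,
    structural and pairwise-discrimination validators for tag sets, a
    deterministic tag-set generator, an in-silico mispriming and amplicon
    screen against background sequence collections, assembly of tagged SSR
    assays and allele-specific (ASO/LSO) SNP assays, single-tube multiplex
    panel construction with exclusive dye labeling checked by a rule-based
    two-stage PCR simulation, and a seeded fixture generator for fully
    offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
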