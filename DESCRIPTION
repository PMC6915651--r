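Package: coiRFLP
Title: In Silico COI Barcode RFLP Design and Seafood Species Authentication
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design and application of PCR-RFLP assays on cytochrome
    oxidase I (COI) DNA barcodes for species authentication of seafood
    products. Provides IUPAC-aware restriction-site scanning and in
    silico digestion of barcode amplicons, a virtual agarose-gel model
    (minimum visible band size, comigration merging, tolerance-based
    band matching), selection of a single discriminating restriction
    enzyme or a minimal enzyme set for a multi-species reference panel,
    assignment of unknown samples from observed band patterns or
    sequences, barcode quality control (premature stop codon / NUMT
    screening under the vertebrate mitochondrial code, local
    pairwise-identity best-match identification), mislabeling
    reporting, and a seeded generator of synthetic reference panels
    with planted restriction-site layouts for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, SequenceMatching, Classification
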