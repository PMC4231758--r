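Package: telofuse
Title: Detect and Test Telomere-Fusion Signatures in Paired-End Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects interchromosomal mate pairs in paired-end sequencing
    alignments, quantifies how often such pairs involve subtelomeric
    sequence (within a configurable window of a chromosome end), and tests
    whether subtelomere involvement exceeds the expectation under a
    uniform-recombination null, as a read-pair assay for end-to-end
    chromosome fusions. Includes a two-library contingency comparison, a
    seeded paired-end alignment simulator with fusion-junction truth tables
    for end-to-end validation, and tidy (tibble-based) result objects with
    broom-style tidy() and glance() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite,
    withr,
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
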