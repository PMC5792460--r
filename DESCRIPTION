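Package: barcodeval
Title: Evaluation of Multi-Locus DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how well a set of candidate DNA barcode loci
    discriminates closely related species from a reference library of aligned
    sequences, as used when building wood-specimen barcode libraries for
    forensic timber identification. Implements Kimura 2-parameter and
    p-distances under pairwise deletion, barcoding-gap assessment,
    TaxonDNA-style best match and best close match identification,
    neighbor-joining tree construction with bootstrap support and a
    voucher-aware monophyly criterion, exhaustive ranking of all locus
    combinations, and discovery of species-diagnostic substitution and indel
    blocks for mini-barcode design. A seed-deterministic multi-locus library
    simulator generates test libraries with configurable within- and
    between-species divergence, locus dropout and diagnostic indels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
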