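Package: epiloops
Title: Classification and Integration of Enhancer-Promoter Chromatin Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates and classifies promoter-capture Hi-C and HiChIP chromatin
    interactions by H3K27ac and promoter status (enhancer-promoter,
    promoter-promoter and enhancer-enhancer interactions), builds cross-sample
    core-interaction score matrices with average-linkage clustering and PCA,
    calls consensus differential H3K27ac regions from peak sets, and integrates
    interaction classes at the gene level with expression changes, drug
    sensitivity enrichment and Bliss synergy scoring of drug combinations.
    Ships a seeded synthetic-study generator with planted ground truth for
    end-to-end validation of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    withr,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
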