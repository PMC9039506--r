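Package: graftmobile
Title: Graft-Mobile mRNA Detection and Multi-Omics Integration in Heterografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects graft-mobile mRNAs between two grafted species from
    short-read data using species-diagnostic substitution sites, classifies
    their movement direction and chilling response, calls differential genes
    and metabolites with a heterograft-versus-homograft difference-of-
    differences (delta2 - delta1) log2 fold-change statistic, and integrates
    mobile mRNAs, differentially expressed genes and differentially intense
    metabolites into correlation and pathway networks. Ships a synthetic-data
    generator with planted ground truth (homolog pairs with tunable
    divergence, 150-bp reads, a full graft x tissue x condition expression
    design, intensity tables and pathway annotation) so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
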