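Package: allelemir
Title: Allele-Aware Analysis of miRNA Binding to Polymorphic 3'UTRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs per-allele 3' untranslated regions (3'UTRs) from a
    reference transcript plus SNP/indel haplotypes, classifies UTR haplotype
    types under a global-frequency filter, detects canonical microRNA seed
    sites (8mer, 7mer-m8, 7mer-A1), scores miRNA:target hybridization energy
    with an embedded Turner 2004 nearest-neighbor model, quantifies per-SNP
    allele impact (delta-MFE, gain/loss of binding sites), folds UTRs (Zuker
    minimum free energy and McCaskill base-pair probabilities) to score
    seed-site accessibility, and groups UTR types with neighbor-joining trees.
    Includes a constraint-based synthetic data generator emulating the MICA
    3'UTR system (frameshifting indels, premature stop codons, planted seed
    sites) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    ape,
    Biostrings,
    generics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
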