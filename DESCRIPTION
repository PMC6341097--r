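Package: rarefam
Title: Rare-Variant Prioritization and Association Testing in Multiplex Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for family-based rare-variant studies of complex disease:
    prioritization of private protein-altering variants that segregate with
    affection status in multiplex pedigrees, gene-based rare-variant burden
    case-control association with one-sided Fisher exact tests and
    conditional maximum-likelihood odds ratios, a sibling-based
    transmission-disequilibrium burden test with Yates-corrected chi-square,
    and size-bounded gene-set overrepresentation analysis with
    Benjamini-Hochberg false-discovery control. Includes a synthetic
    pedigree and cohort simulator with recorded ground truth so every
    analysis stage can be exercised without access to restricted subject
    data, plus readers and writers for PED, VCF, annotation TSV and GMT
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
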