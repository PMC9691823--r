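Package: revphen
Title: Reverse-Phenotyping Diagnostic Workflow for Rare-Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genotype-first ("reverse phenotyping") research diagnostic
    pipeline for large sequenced cohorts, built around a curated panel of
    multisystemic ciliopathy genes. From annotated small-variant calls,
    cohort structural-variant calls, pedigrees and sparse Human Phenotype
    Ontology profiles, the package prioritises rare variants against a
    disease-specific maximum credible population allele frequency, screens
    structural variants by cohort rarity and read support, screens rare
    variants for predicted splice effects, assembles inheritance-consistent
    candidate diagnoses, matches them against a gene-syndrome knowledge base
    of weighted key clinical features, and classifies reportability and
    diagnostic confidence from curator-supplied ACMG variant classes. A
    seeded synthetic-cohort generator with a truth table makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    yaml,
    igraph,
    vcfR,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    generics,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
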