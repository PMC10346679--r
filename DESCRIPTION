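Package: triohet
Title: Trio Expression Analysis of Heterosis in Hybrid Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of heterosis from parent/parent/hybrid (trio) RNA-seq
    experiments and phenotype tables. Computes mid-parent and high-parent
    heterosis with significance tests, FPKM normalization and differential
    expression calling, additive/dominance decomposition of per-gene
    expression with potency-ratio classification of the mode of inheritance,
    derivation of hybrid-specific temporal response gene sets (SDG, SDG_hp,
    SSDG_hp) and Venn-region counts, weighted gene co-expression network
    analysis (soft-threshold adjacency, topological overlap, module
    detection, module eigengenes, module-trait correlation), and
    hypergeometric over-representation analysis with FDR control. Includes a
    negative-binomial trio simulator with planted ground truth so every
    stage can be validated on data with known structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
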