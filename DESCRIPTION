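Package: burdensea
Title: Two-Step Rare- and Common-Variant Association via Gene Collapsing and Set Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-level collapsing association tests for quantitative traits
    (CMC carrier-indicator and allele-count variants, and two weighted-sum
    variants) combined with gene-set enrichment analysis of the resulting
    gene scores. Implements the classical running-sum (GSEA-style) enrichment
    statistic and a variant (VSEA) that first standardizes each gene's score
    by its own phenotype-permutation null distribution, correcting for
    gene-size and allele-frequency-composition differences. Includes a
    replicate-frequency filter for spurious genes, a synthetic-data generator
    for mixed rare/common architectures with optional cross-gene confounding,
    and an evaluation harness estimating false-positive rates and power
    across phenotype replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
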