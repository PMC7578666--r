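Package: chemsens
Title: Gene and Pathway Sensitivity to Chemical Exposures from
    Chemical-Gene Interaction Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the sensitivity of genes and molecular pathways to
    chemical exposures from curated chemical-gene interaction records of the
    kind distributed by the Comparative Toxicogenomics Database. Interaction
    tables are read, validated against an eleven-term chemical-use
    vocabulary, restricted to human, mouse and rat evidence, filtered to
    genes shared by all three genomes, and deduplicated to unique
    (study, model, chemical, gene) combinations. Per-gene interaction counts
    serve as a sensitivity statistic; the ranked counts are mean-centered so
    positive and negative areas under the rank curve are equal, and the
    centered ranking is analysed by preranked gene-set enrichment with a
    weighted running-sum statistic, gene-set permutation null, size-normalised
    enrichment scores and a sign-stratified FDR q-value. A synthetic-data
    generator with planted high- and low-sensitivity gene sets supports
    end-to-end benchmarking, and a pipeline driver produces deterministic,
    auditable artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    ggplot2,
    optparse
Config/testthat/edition: 3
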