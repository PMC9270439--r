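Package: funscape
Title: Gene Function Prediction from Local Functional Landscapes of Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Gene Ontology annotations for genes using only their
    relative location in the genome. Each chromosomal arm is modelled as an
    ordered string of protein-coding genes; local enrichment of GO terms in
    gene-count windows around every gene yields per-gene Functional Landscape
    Arrays, which feed one random-forest classifier per ontology term. Scores
    are made consistent with the ontology DAG and evaluated with hierarchical
    precision, recall and F-max against a term-frequency null model. Includes
    a synthetic-genome generator with tunable spatial clustering of
    functionally related genes, an end-to-end pipeline, and tidy accessors
    and ggplot2 visualisations for every result type.
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
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    rtracklayer,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
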