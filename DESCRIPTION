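Package: genesum
Title: Rule-Based Generation of Concise Gene Summaries from Structured Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates short English gene summaries for nematode genes from
    structured, curated annotations: Gene Ontology annotations (GAF 2.2),
    disease and anatomy-ontology expression annotations, orthology tables with
    prediction-method support, collated large-scale expression and regulation
    records, and InterPro protein-domain tables. Implements ortholog-based
    annotation transfer (human orthologs for C. elegans genes, best related
    nematode orthologs otherwise), gating rules that admit transferred,
    large-scale and domain statements only for genes lacking curated data,
    controlled-vocabulary sentence templating with exemplar truncation, and
    deterministic txt/json/tsv writers. Ships a fixture generator that rebuilds
    worked example inputs and seeded random annotation bundles, plus a small
    command-line interface.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
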