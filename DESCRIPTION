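Package: semmap
Title: Assembly and Reasoning over Semantic Mappings Between Biomedical Identifier Resources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ingests heterogeneous semantic mapping sets (SSSOM TSV and bare
    cross-reference tables), represents them as a directed, evidence-bearing
    mapping graph, infers new mappings by inversion, predicate mutation and
    transitive predicate chaining with noisy-OR confidence propagation, filters
    inconsistent or low-confidence mappings, and assembles projection and
    prioritization mapping sets for biomedical identifier standardization.
    Includes a seeded synthetic fixture generator with planted equivalence
    cliques and known ground truth, a declarative YAML pipeline, and exports to
    SSSOM and a property-graph file layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    openssl,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
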