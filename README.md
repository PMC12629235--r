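# semmap

Assembly and reasoning over semantic mappings between biomedical identifier
resources.

Biomedical entities — genes, chemicals, diseases, cell types, cell lines —
are catalogued by many overlapping ontologies and databases, each with its
own identifier space. Integrating data across them requires *semantic
mappings* (`skos:exactMatch`, `skos:broadMatch`, database cross-references,
…) between identifiers, but available mappings are fragmented: no single
source connects every pair of resources, predicates vary in precision, and
provenance and confidence metadata are inconsistent. `semmap` is for data
engineers and ontologists who need to assemble such mappings into consistent,
confidence-annotated artifacts for identifier standardization.

## What it does

* **Model.** Mappings are unique `(subject, predicate, object)` triples of
  registry-validated CURIEs, each carrying one or more evidence objects —
  provenance leaves (justification, author, producer confidence, mapping set)
  or inference nodes pointing at the supporting mappings. Everything is
  identified by deterministic SHA-256 content hashes.
* **Confidence.** A noisy-OR calculus: evidence combines the consumer's
  confidence in a mapping set with the producer's published confidence as
  `c_e = 1 − (1 − c_set)(1 − c_prod)`; a mapping's confidence over evidences
  `E` is `c_m = 1 − ∏(1 − c_e)`; inferred evidence over supports `M` is
  `c_e = γ_op (1 − ∏(1 − c_m))` with an operation-specific factor `γ_op`.
* **Inference.** Inversion (reverse edge under the inverse predicate),
  mutation (parallel edge under a replacement predicate, e.g. promoting
  implicit-exact cross-references), and transitive chaining (predicate
  composition along paths under SKOS-style chain rules), all with reasoned
  evidence and blocked by curated negative mappings.
* **Filtering/QA.** Prefix and prefix-pair exclusions, confidence
  thresholds, negative-mapping subtraction, and cardinality flagging of
  entities mapping to multiple terms in one resource.
* **Assembly.** Projection mapping sets (functional, prefix-pure maps from
  one identifier space to another) and prioritization mapping sets (a star
  graph per clique of equivalent entities, sending every member to the
  canonical identifier chosen by a prefix priority list).
* **I/O.** SSSOM TSV read/write (round-trip faithful), bare cross-reference
  TSV ingestion, property-graph node/edge TSV export, and a declarative YAML
  pipeline with a thin CLI (`inst/cli/assemble`).
* **Fixtures.** A seeded synthetic generator that plants equivalence cliques
  with configurable noise and known ground truth.

## Worked example

The shipped toy landscape models six cell-line resources describing one
astrocytoma cell line. A tissue-ontology entry (`tbto:0000058`) and a
cell-line-ontology entry (`tclo:0001072`) have no direct mapping anywhere —
connecting them requires promoting a database cross-reference to an exact
match and chaining through two intermediate resources.

```r
library(semmap)

doc <- toy_cell_line_doc()
doc
#> <mapping_document> 7 mapping(s), 7 evidence(s), 2 mapping set(s), 6 prefix(es)

processed <- full_process(doc,
  mutations = list(mutation_rule(PRED_XREF, PRED_EXACT, factor = 0.7)))
attr(processed, "processing_log")
#> # A tibble: 4 x 3
#>   stage      n_mappings n_evidences
#>   <chr>           <int>       <int>
#> 1 input               7           7
#> 2 mutations           8           8
#> 3 inversions         16          16
#> 4 chains             32          68
```

The missing mapping now exists, supported by a shortest chain of three
mappings (tissue entry → experimental-factor entry → knowledgebase entry →
ontology entry), and the six raw terms collapse to one canonical entity:

```r
m <- processed$mappings[[mapping_hash("tbto:0000058", PRED_EXACT, "tclo:0001072")]]
min(vapply(m$evidences, function(e) length(e$supports), integer(1)))
#> [1] 3

reduction_stats(processed)
#> # A tibble: 1 x 4
#>   raw_terms unique_terms reduction_pct n_cliques
#>       <int>        <int>         <dbl>     <int>
#> 1         6            1          83.3         1
```

`raw_terms` counts distinct entities; merging each clique to one canonical
term leaves `unique_terms`; `reduction_pct` is the percentage of terms that
integration removed. Prioritizing against a preference order standardizes
any member to the canonical identifier:

```r
ps <- build_prioritization(processed,
  priority = c("tcell", "tefo", "tdep", "tccle", "tclo", "tbto"))
ps
#> <prioritization_set> 6 entities -> 1 canonical, priority: tcell > tefo > tdep > tccle > tclo > tbto
standardize(ps, c("tclo:0001072", "tbto:0000058"))
#> [1] "tcell:0110" "tcell:0110"
```

The same run is available declaratively: `inst/extdata/demo/config.yaml`
ingests the toy SSSOM file, applies the mutation/inversion/chaining stages,
and writes SSSOM, prioritization, projection and property-graph outputs
(`Rscript inst/cli/assemble run config.yaml` from a copy of that directory).

## Layout

* `R/` — model, hashing, confidence, SSSOM/property-graph I/O, inference,
  filters, assembly, pipeline, fixtures
* `vignettes/semantic-mapping-assembly.Rmd` — the methods write-up: model
  assumptions, parameter semantics, design decisions, limitations
* `tests/testthat/` — unit, property and end-to-end suites with independent
  oracles
* `inst/cli/assemble` — CLI verbs `run`, `convert`, `cardinality`,
  `standardize`, `fixtures`
* `inst/extdata/demo/` — the shipped toy pipeline
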