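---
title: "Assembling and reasoning over semantic mappings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling and reasoning over semantic mappings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semmap)
```

## The problem

Biomedical entities — genes, chemicals, diseases, cell lines, anatomical
structures — are catalogued by many partially overlapping ontologies and
databases, each with its own identifier space. Integrating data across these
resources requires *semantic mappings*: triples asserting that an entity in
one identifier space is an exact, close, broader, narrower or related match
of an entity in another. Available mappings are fragmented across sources,
use predicates of varying precision (many resources publish only
low-precision database cross-references), and rarely connect every pair of
resources directly, so equivalences must often be *inferred* through chains
of mappings while tracking where each inference came from and how much to
trust it.

`semmap` models a mapping collection as a directed graph whose edges carry
evidence, infers missing mappings by inversion, predicate mutation and
transitive chaining, filters mappings that would corrupt integration, and
assembles two standard artifacts: **projection mapping sets** (one identifier
space mapped functionally onto another) and **prioritization mapping sets**
(every entity standardized to one canonical identifier).

## The data model

A **mapping** is a unique `(subject, predicate, object)` triple. Subjects and
objects are CURIEs validated against a prefix registry (prefixes are
normalized to canonical casing; local identifiers are never rewritten —
validation, not rewriting). Predicates come from an extensible vocabulary
(`default_vocabulary()`) covering the SKOS match predicates, OWL class
equivalence, the database cross-reference predicate, and the
gene/gene-product pair; each predicate declares its inverse, and the inverse
table is an involution. Directionality is explicit: `(A, p, B)` and
`(B, p, A)` are distinct mappings even for symmetric `p`, which is what makes
the provenance of inversion trackable.

Each mapping carries one or more **evidence** objects:

* **simple evidence** is a provenance leaf: a mapping-justification term, an
  optional author (ORCID), an optional producer confidence, and a reference
  to the **mapping set** it came from (a named, versioned, licensed source
  with a *consumer confidence* — the assembling user's prior that an
  arbitrary mapping from that source is correct);
* **reasoned evidence** is an inference node: the operation (`inversion`,
  `mutation`, `chain`, `prioritization`), an ordered list of supporting
  mappings, and an operation-specific scaling factor $\gamma_{op}$.

Ingesting a duplicate triple merges evidence onto the existing mapping;
identical evidence content deduplicates by content hash. The provenance
structure (evidence pointing at mappings pointing at evidence) must be a DAG;
cycles are detected and rejected during confidence computation.

## The confidence calculus

All confidences are probabilities in $[0,1]$ combined by noisy-OR, i.e. the
probability that at least one of several independent supports is correct:

* simple evidence: $c_e = 1 - (1 - c_{\mathrm{set}})(1 - c_{\mathrm{prod}})$.
  When the producer published no confidence, the value is *absent* — not 0,
  not 1 — and the computation takes an explicit fallback branch returning
  $c_{\mathrm{set}}$ exactly. This is numerically identical to assuming a
  producer confidence of 1 but keeps absence auditable in the data.
* mapping over evidences $E$: $c_m = 1 - \prod_{e \in E}(1 - c_e)$, monotone
  non-decreasing in each $c_e$ and under evidence growth.
* reasoned evidence over supporting mappings $M$:
  $c_e = \gamma_{op}\,\bigl(1 - \prod_{m \in M}(1 - c_m)\bigr)$.

The independence assumption is a modelling idealization: two mapping sets
that both scraped the same upstream resource are not independent witnesses,
so noisy-OR confidences are upper bounds in the presence of shared ancestry.

One design choice needs stating: reasoned evidence snapshots the noisy-OR of
its supports at creation time. The live recursion over the provenance DAG is
authoritative whenever all supports still resolve, but if a later filter
removes a supporting mapping, the snapshot keeps the evidence's confidence
well-defined instead of leaving dangling provenance an error. Filters remove
assertions, not the historical fact that an inference was drawn from them.

## Content hashing

Mappings, evidences and mapping sets are identified by SHA-256 digests of a
canonical serialization (fixed field order, unit-separator delimiter with an
escape scheme, UTF-8, `%.17g` for numbers; the exact layout is documented in
`` ?`content-hashing` ``). A mapping's identity covers *only its triple*: merging
evidence onto a unique triple would be impossible if identity included
evidence content. Evidence hashes cover their full content including the
mapping-set hash; mapping-set hashes cover name/version/license but not the
consumer confidence, which is the consumer's opinion rather than the set's
content. The algorithm name (`sha256`) is recorded in every export so
digests are comparable across implementations.

## Inference

**Inversion** adds, for each mapping `(A, p, B)` lacking a counterpart, the
edge `(B, inv(p), A)` with reasoned evidence supported by the original.
$\gamma = 1$ by default: inversion is lossless logic. A second pass is a
fixpoint.

**Mutation** adds a parallel edge with a replacement predicate under
configured rules, optionally scoped to a subject/object prefix pair.
Generalizations (equivalence → exact match) default to $\gamma = 1$;
strengthenings (cross-reference → exact match, gene/gene-product → exact
match) encode genuine epistemic risk and have *no default* — the user must
own the factor explicitly.

**Chaining** composes predicates along simple paths (no node revisited) of
length 2..`max_path_length` under a total chain-rule table
(`default_chain_rules()`): exact matches compose with everything listed and
act as identity; broad∘broad = broad, narrow∘narrow = narrow, broad and
narrow in sequence compose to nothing; close and related compose only with
exact; database cross-references compose with nothing and must be mutated
first. The table ships as editable data because the community convention
names the rules without fixing a closed list. Each supporting path becomes
its own reasoned evidence on the single inferred triple, which makes the
inferred confidence independent of path discovery order (noisy-OR is
commutative). Paths never step through curated negative triples. A path
whose running composition reaches "nothing" stops: composition with nothing
is absorbing, so no extension can recover.

`max_path_length` defaults to 5: with inversion materializing both
directions, that closes cliques of the diameters seen in practice while
keeping traversal bounded and deterministic. Nodes and edges are processed
in lexicographic CURIE order throughout, so outputs are byte-stable. When a
node pair accumulates both an exact and a weaker composed predicate, both
triples are kept; adjudication is deferred to the cardinality and confidence
filters rather than resolved during traversal.

## Filtering and quality assurance

Filters remove mappings by subject prefix, object prefix or prefix pair
(prior knowledge such as "disease terms must never map to gene databases"),
by confidence threshold, and by subtracting curated negative mappings (which
also block chain steps). Every filter returns retained and removed sets that
exactly partition its input.

Cardinality checking finds entities with exact matches to more than one
entity in a single target prefix — structures that make consistent merging
impossible. The default is to *flag* these into a TSV report (one row per
participating mapping with a violation-group key, hand-editable into a
negatives file) rather than delete, because such conflicts are curation
opportunities; an opt-in mode deletes the whole violating group, never a
heuristic subset. Assessment is directional by default, matching the
directed graph model, with an undirected mode for symmetric predicates.
Whether cardinality QA runs before or after inference is a pipeline-config
choice, not fixed: both orders are legitimate (before: audit the sources;
after: audit the integration result).

## Assembly

A **clique** is implemented as a connected component of the exact-match
subgraph. After chaining, components and true cliques coincide; component
semantics additionally tolerate incomplete closure (e.g. a `max_path_length`
smaller than a clique's diameter). Weaker-than-exact edges inside a
component are ignored for membership; the alternative (letting broad/narrow
edges glue components) would conflate equivalence with relatedness.

**Prioritization** requires a priority list of prefixes. Per clique, the
canonical entity is the member whose prefix comes earliest in the list; every
member maps onto it, the canonical entity maps to itself, and each entity
appears as subject exactly once — a star graph per clique, checked by
`star_graph_check()`. A clique holding two entities of one prefix violates
the one-entity-per-prefix assumption: the default is a hard error;
configuration may exclude the clique with a log entry or demote it to the
next priority prefix that is a singleton within it. Entities that appear in
no exact-match mapping are omitted (the package can only see entities that
mappings mention, so per-prefix term counts are lower bounds unless a full
term list is supplied).

**Projection** onto a prefix pair keeps all exact-match mappings with the
right subject and object prefixes — whether directly asserted or inferred —
and excludes (with a report) any subject with more than one object, so the
result is functional and prefix-pure by construction.

The **reduction** metric reported by the pipeline is
$(\mathrm{raw} - \mathrm{unique})/\mathrm{raw} \times 100$ where
$\mathrm{unique} = \mathrm{raw} - (\text{clique members} - \text{cliques})$:
the percentage of raw terms that merging equivalents removes.

## The synthetic fixture generator

`generate_fixtures()` plants cliques of cross-prefix equivalent entities
(one entity per prefix per clique) and emits, per source, only a random
spanning tree of each clique — so recovering full cliques genuinely requires
inversion and chaining, as in real mapping landscapes. Noise dials emulate
the main real-world failure modes: `dropout` (missing mappings),
`wrong_edge_rate` (edges fusing distinct cliques — the failure cardinality
QA must catch), `m2m_rate` (duplicate terms in one resource creating
many-to-many structures, recorded as planted violations), and
`imprecise_rate` (exact matches demoted to database cross-references, which
must be mutated back before chaining). All draws are governed by the spec's
seed, restored on exit so the session RNG stream is untouched; identical
seeds give byte-identical fixtures. Fixture CURIEs use reserved `fx*`
prefixes registered in the frozen in-package registry, never real resource
prefixes, so fixtures can never be mistaken for semantic claims.

What the generator does *not* emulate: realistic identifier syntax, skewed
source sizes, correlated errors between sources, predicate mixtures beyond
exact/cross-reference, or lexical ambiguity. Passing the planted-recovery
tests therefore shows the algorithms are correct on the failure modes
modelled, not that any particular real resource pair would integrate
cleanly.

The worked example `toy_cell_line_doc()` is a hand-built six-resource
landscape around one astrocytoma cell line, with a cross-reference edge that
must be mutated and a tissue-ontology entry reachable from the cell-line
ontology only through a three-step chain — the canonical demonstration that
direct mappings alone cannot connect fragmented resources.

## Verification sizes and numerical choices

The test suite and the acceptance script recompute every guarantee from
scratch at these problem sizes, chosen to exercise the combinatorics while
keeping a full run on one CPU in minutes: 10,000 random draws for the
confidence calculus against a brute-force Bernoulli enumeration oracle
(agreement within $10^{-12}$; observed error is at machine precision); 500
random directed graphs of up to 12 nodes for chain closure against an
exhaustive path-enumeration oracle (exact triple-set equality); 100 seeds of
noise-free planted cliques for exact recovery and reduction bookkeeping; and
smaller corpora for round-trip, property-graph closure, determinism and
hash-collision checks. Comparisons of confidences use exact equality where
the computation is deterministic and $10^{-12}$ tolerances where two
algebraically equal formulas are evaluated in different orders.

Degenerate inputs are defined behaviour, not errors: empty documents
round-trip and export header-only files; filters matching nothing are the
identity; negatives referencing absent triples are a logged no-op; a
singleton entity standardizes to itself.

## Limitations

* Noisy-OR assumes independent evidence; shared upstream provenance inflates
  confidence.
* Chaining is bounded by `max_path_length`; cliques of larger diameter close
  only partially (component-based clique extraction then still groups them).
* The cardinality checker flags inconsistencies but cannot adjudicate which
  member of a many-to-many group is correct — that remains curation.
* Alternative/replaced-by identifier annotations and term splitting/merging
  histories are out of scope.
* The shipped registry is a frozen subset; production use should supply a
  registry built from a community prefix resource.
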