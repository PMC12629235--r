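# Inversion, mutation and transitive chaining over the mapping graph.

test_that("inversion adds the reverse edge under the inverse predicate", {
  doc <- doc_from_edges(tibble::tibble(
    subject = c("fx1:a", "fx1:a"),
    predicate = c(PRED_EXACT, PRED_NARROW),
    object = c("fx2:b", "fx3:c")
  ))
  inv <- infer_inversions(doc)
  tri <- doc_triples(inv)
  expect_true(mapping_hash("fx2:b", PRED_EXACT, "fx1:a") %in% tri$hash)
  # a narrow match inverts to a broad match
  expect_true(mapping_hash("fx3:c", PRED_BROAD, "fx1:a") %in% tri$hash)
  expect_identical(n_mappings(inv), 4L)

  # the new mappings carry reasoned evidence pointing at the originals
  m <- inv$mappings[[mapping_hash("fx2:b", PRED_EXACT, "fx1:a")]]
  e <- m$evidences[[1]]
  expect_identical(e$operation, "inversion")
  expect_identical(e$supports, mapping_hash("fx1:a", PRED_EXACT, "fx2:b"))

  # applying inversion twice is a fixpoint
  inv2 <- infer_inversions(inv)
  expect_identical(sort(names(inv2$mappings)), sort(names(inv$mappings)))
  expect_identical(n_evidences(inv2), n_evidences(inv))
})

test_that("existing counterparts gain no duplicate on inversion", {
  doc <- doc_from_edges(tibble::tibble(
    subject = c("fx1:a", "fx2:b"), predicate = PRED_EXACT,
    object = c("fx2:b", "fx1:a")
  ))
  inv <- infer_inversions(doc)
  expect_identical(n_mappings(inv), 2L)
  expect_identical(n_evidences(inv), 2L)
})

test_that("mutation adds a parallel edge under the target predicate", {
  doc <- doc_from_edges(tibble::tibble(
    subject = "fx1:a", predicate = PRED_EQUIV, object = "fx2:b"
  ))
  out <- apply_mutations(doc, list(mutation_rule(PRED_EQUIV, PRED_EXACT)))
  tri <- doc_triples(out)
  expect_setequal(tri$predicate, c(PRED_EQUIV, PRED_EXACT))
  m <- out$mappings[[mapping_hash("fx1:a", PRED_EXACT, "fx2:b")]]
  e <- m$evidences[[1]]
  expect_identical(e$operation, "mutation")
  expect_identical(e$factor, 1)

  # empty rule list leaves the graph unchanged
  expect_identical(names(apply_mutations(doc, list())$mappings), names(doc$mappings))
  expect_error(apply_mutations(doc, list(mutation_rule("skos:bogus", PRED_EXACT))),
               class = "semmap_config_error")
})

test_that("prefix-scoped strengthening rules fire only in scope", {
  doc <- doc_from_edges(tibble::tibble(
    subject = c("fx1:g1", "fx3:g2"),
    predicate = PRED_HAS_GENE_PRODUCT,
    object = c("fx2:p1", "fx4:p2")
  ))
  rule <- mutation_rule(PRED_HAS_GENE_PRODUCT, PRED_EXACT, factor = 0.8,
                        subject_prefix = "fx1", object_prefix = "fx2")
  out <- apply_mutations(doc, list(rule))
  tri <- doc_triples(out)
  expect_true(mapping_hash("fx1:g1", PRED_EXACT, "fx2:p1") %in% tri$hash)
  expect_false(mapping_hash("fx3:g2", PRED_EXACT, "fx4:p2") %in% tri$hash)
  # the strengthening factor caps the inferred mapping's confidence
  m <- out$mappings[[mapping_hash("fx1:g1", PRED_EXACT, "fx2:p1")]]
  expect_lte(mapping_confidence(m, out), 0.8)
})

test_that("chaining composes predicates along paths per the rule table", {
  # A exact B, B exact C -> A exact C
  doc <- doc_from_edges(tibble::tibble(
    subject = c("fx1:a", "fx2:b"), predicate = PRED_EXACT,
    object = c("fx2:b", "fx3:c")
  ))
  out <- infer_chains(doc)
  expect_true(mapping_hash("fx1:a", PRED_EXACT, "fx3:c") %in% names(out$mappings))

  # A exact B, B broad C -> A broad C
  doc2 <- doc_from_edges(tibble::tibble(
    subject = c("fx1:a", "fx2:b"),
    predicate = c(PRED_EXACT, PRED_BROAD),
    object = c("fx2:b", "fx3:c")
  ))
  out2 <- infer_chains(doc2)
  expect_true(mapping_hash("fx1:a", PRED_BROAD, "fx3:c") %in% names(out2$mappings))

  # A broad B, B narrow C composes to nothing
  doc3 <- doc_from_edges(tibble::tibble(
    subject = c("fx1:a", "fx2:b"),
    predicate = c(PRED_BROAD, PRED_NARROW),
    object = c("fx2:b", "fx3:c")
  ))
  out3 <- infer_chains(doc3)
  expect_identical(n_mappings(out3), 2L)

  expect_error(infer_chains(doc, max_path_length = 1), class = "semmap_config_error")
})

test_that("multiple paths to one triple merge as multiple evidences", {
  doc <- doc_from_edges(tibble::tibble(
    subject = c("fx1:a", "fx2:b", "fx1:a", "fx3:c"),
    predicate = PRED_EXACT,
    object = c("fx2:b", "fx4:d", "fx3:c", "fx4:d")
  ))
  out <- infer_chains(doc)
  m <- out$mappings[[mapping_hash("fx1:a", PRED_EXACT, "fx4:d")]]
  expect_identical(length(m$evidences), 2L)
  expect_true(all(vapply(m$evidences, function(e) e$operation, character(1)) == "chain"))
})

test_that("chain closure equals the exhaustive path-enumeration oracle", {
  set.seed(101)
  rules <- default_chain_rules()
  for (i in 1:40) {
    n <- sample(4:10, 1)
    doc <- random_mapping_graph(n, sample(4:12, 1))
    doc <- infer_inversions(doc)
    L <- sample(2:4, 1)
    got <- inferred_triples(infer_chains(doc, rules, max_path_length = L), doc)
    want <- oracle_chain_closure(doc, rules, L)
    expect_identical(got, want)
  }
})

test_that("negative triples block chain steps", {
  doc <- doc_from_edges(tibble::tibble(
    subject = c("fx1:a", "fx2:b"), predicate = PRED_EXACT,
    object = c("fx2:b", "fx3:c")
  ))
  neg <- tibble::tibble(subject = "fx2:b", predicate = PRED_EXACT, object = "fx3:c")
  out <- infer_chains(doc, negatives = neg)
  expect_false(mapping_hash("fx1:a", PRED_EXACT, "fx3:c") %in% names(out$mappings))
})

test_that("inferred confidence never exceeds the operation factor", {
  set.seed(11)
  doc <- random_mapping_graph(8, 10)
  doc <- infer_inversions(doc)
  out <- infer_chains(doc, factor = 0.6)
  new <- setdiff(names(out$mappings), names(doc$mappings))
  for (h in new) {
    m <- out$mappings[[h]]
    only_chain <- all(vapply(m$evidences, function(e) e$type == "reasoned", logical(1)))
    if (only_chain && length(m$evidences) == 1L) {
      expect_lte(mapping_confidence(m, out), 0.6 + 1e-12)
    }
  }
})

test_that("full processing reaches a closure fixpoint on the toy landscape", {
  doc <- toy_cell_line_doc()
  mut <- list(mutation_rule(PRED_XREF, PRED_EXACT, factor = 0.7))
  p1 <- full_process(doc, mutations = mut)
  p2 <- full_process(p1, mutations = mut)
  expect_identical(sort(names(p2$mappings)), sort(names(p1$mappings)))

  # no inference, no filters: identity on triples
  ident <- full_process(doc, inversions = FALSE, chains = NULL)
  expect_identical(sort(names(ident$mappings)), sort(names(doc$mappings)))
})

test_that("the toy landscape only connects its ontology entries via a multi-hop chain", {
  doc <- toy_cell_line_doc()
  target <- mapping_hash("tbto:0000058", PRED_EXACT, "tclo:0001072")
  expect_false(target %in% names(doc$mappings))
  # without the cross-reference mutation the connection cannot be made
  no_mut <- full_process(doc)
  expect_false(target %in% names(no_mut$mappings))
  out <- full_process(doc, mutations = list(mutation_rule(PRED_XREF, PRED_EXACT, factor = 0.7)))
  expect_true(target %in% names(out$mappings))
  m <- out$mappings[[target]]
  lens <- vapply(m$evidences, function(e) length(e$supports), integer(1))
  expect_identical(min(lens), 3L)
  # provenance grounds out in the pre-inference graph
  expect_silent(validate_document(out))
})

test_that("equally-long support paths give order-invariant confidences", {
  edges <- tibble::tibble(
    subject = c("fx1:a", "fx2:b", "fx1:a", "fx3:c"),
    predicate = PRED_EXACT,
    object = c("fx2:b", "fx4:d", "fx3:c", "fx4:d")
  )
  out1 <- infer_chains(doc_from_edges(edges))
  out2 <- infer_chains(doc_from_edges(edges[c(3, 4, 1, 2), ]))
  h <- mapping_hash("fx1:a", PRED_EXACT, "fx4:d")
  expect_equal(mapping_confidence(out1$mappings[[h]], out1),
               mapping_confidence(out2$mappings[[h]], out2))
})
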