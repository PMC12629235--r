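# Core data model: CURIE validation, confidence calculus, content hashing.

test_that("CURIE validation normalizes prefixes and preserves local ids", {
  reg <- default_registry()
  r <- validate_reference("CLO:0001072", reg)
  expect_s3_class(r, "semmap_reference")
  expect_identical(r$prefix, "clo")
  expect_identical(r$local_id, "0001072")
  expect_identical(r$curie, "clo:0001072")

  r2 <- validate_reference("hgnc:9588", reg)
  expect_identical(r2$curie, "hgnc:9588")

  # equality is on normalized content
  expect_identical(validate_reference("HGNC:9588", reg)$curie, r2$curie)

  empty <- semmap:::new_prefix_registry(setNames(list(), character()))
  expect_error(validate_reference("notaprefix:123", empty), class = "semmap_unknown_prefix")
  expect_error(validate_reference("nocolon", reg), class = "semmap_curie_error")
  expect_error(validate_reference(":123", reg), class = "semmap_curie_error")
})

test_that("bulk CURIE normalization is strict or lenient on demand", {
  reg <- default_registry()
  expect_identical(normalize_curies(c("CLO:1", "hgnc:2"), reg), c("clo:1", "hgnc:2"))
  expect_error(normalize_curies(c("clo:1", "bogus:2"), reg), class = "semmap_curie_error")
  expect_warning(out <- normalize_curies(c("clo:1", "bogus:2"), reg, strict = FALSE))
  expect_identical(out, c("clo:1", NA))
})

test_that("the predicate inverse table is an involution over the vocabulary", {
  vocab <- default_vocabulary()
  inv <- invert_predicate(vocab$predicate, vocab)
  expect_identical(invert_predicate(inv, vocab), vocab$predicate)
  # symmetric predicates are their own inverse
  sym <- vocab$predicate[vocab$symmetric]
  expect_identical(invert_predicate(sym, vocab), sym)
  expect_error(invert_predicate("skos:bogus", vocab), class = "semmap_vocabulary_error")
})

test_that("simple evidence confidence follows the noisy-OR of set and producer", {
  set9 <- mapping_set("s", 0.9)
  doc <- add_mapping_set(mapping_document(), set9)

  # absent producer confidence collapses to the consumer's set confidence
  expect_identical(evidence_confidence(simple_evidence(set9), doc), 0.9)
  # both present: 1 - (1 - 0.9)(1 - 0.5) = 0.95
  expect_equal(evidence_confidence(simple_evidence(set9, confidence = 0.5), doc), 0.95)
  # a certain factor forces certainty
  set1 <- mapping_set("t", 1.0)
  doc <- add_mapping_set(doc, set1)
  expect_identical(evidence_confidence(simple_evidence(set1, confidence = 0.0), doc), 1.0)
})

test_that("mapping confidence is the noisy-OR over evidences", {
  mk_doc <- function(confs) {
    doc <- mapping_document()
    evs <- lapply(seq_along(confs), function(i) {
      s <- mapping_set(paste0("s", i), confs[[i]])
      doc <<- add_mapping_set(doc, s)
      simple_evidence(s)
    })
    doc <- add_mapping(doc, new_mapping("fx1:a", PRED_EXACT, "fx2:b", evs))
    doc
  }
  d1 <- mk_doc(0.7)
  expect_equal(mapping_confidence(d1$mappings[[1]], d1), 0.7)
  d2 <- mk_doc(c(0.5, 0.5))
  expect_equal(mapping_confidence(d2$mappings[[1]], d2), 0.75)
  d3 <- mk_doc(c(0.3, 1.0))
  expect_identical(mapping_confidence(d3$mappings[[1]], d3), 1.0)
  empty <- new_mapping("fx1:a", PRED_EXACT, "fx2:b")
  expect_error(mapping_confidence(empty, mapping_document()), class = "semmap_invariant_error")
})

test_that("reasoned evidence confidence scales the noisy-OR of its supports", {
  set <- mapping_set("s", 1.0)
  doc <- add_mapping_set(mapping_document(), set)
  mk <- function(s, o, conf) {
    st <- mapping_set(paste0("s", conf), conf)
    doc <<- add_mapping_set(doc, st)
    m <- new_mapping(s, PRED_EXACT, o, list(simple_evidence(st)))
    doc <<- add_mapping(doc, m)
    m$hash
  }
  h8 <- mk("fx1:a", "fx2:b", 0.8)
  expect_equal(evidence_confidence(reasoned_evidence("chain", h8, factor = 1), doc), 0.8)
  h5a <- mk("fx2:b", "fx3:c", 0.5)
  h5b <- mk("fx3:c", "fx4:d", 0.5)
  e <- reasoned_evidence("chain", c(h5a, h5b), factor = 0.9)
  expect_equal(evidence_confidence(e, doc), 0.675)
  expect_identical(evidence_confidence(reasoned_evidence("chain", c(h5a, h5b), factor = 0), doc), 0)
})

test_that("confidence calculus matches the brute-force Bernoulli oracle", {
  set.seed(42)
  for (i in 1:200) {
    c_set <- runif(1)
    c_prod <- if (runif(1) < 0.3) NA_real_ else runif(1)
    s <- mapping_set(paste0("s", i), c_set)
    doc <- add_mapping_set(mapping_document(), s)
    e <- simple_evidence(s, confidence = c_prod)
    got <- evidence_confidence(e, doc)
    expect_equal(got, oracle_simple_evidence(c_set, c_prod), tolerance = 1e-12)
    expect_true(got >= 0 && got <= 1)

    k <- sample(1:4, 1)
    confs <- runif(k)
    doc2 <- mapping_document()
    evs <- lapply(seq_len(k), function(j) {
      st <- mapping_set(paste0("t", j), confs[[j]])
      doc2 <<- add_mapping_set(doc2, st)
      simple_evidence(st)
    })
    m <- new_mapping("fx1:a", PRED_EXACT, "fx2:b", evs)
    doc2 <- add_mapping(doc2, m)
    expect_equal(mapping_confidence(m, doc2), oracle_mapping(confs), tolerance = 1e-12)
  }
})

test_that("mapping confidence is monotone under evidence growth", {
  set.seed(7)
  for (i in 1:50) {
    confs <- runif(sample(1:4, 1))
    extra <- runif(1)
    expect_gte(oracle_mapping(c(confs, extra)), oracle_mapping(confs))
    doc <- mapping_document()
    evs <- lapply(seq_along(confs), function(j) {
      st <- mapping_set(paste0("s", j), confs[[j]])
      doc <<- add_mapping_set(doc, st)
      simple_evidence(st)
    })
    m <- new_mapping("fx1:a", PRED_EXACT, "fx2:b", evs)
    doc <- add_mapping(doc, m)
    before <- mapping_confidence(m, doc)
    st <- mapping_set("extra", extra)
    doc <- add_mapping_set(doc, st)
    doc <- add_evidence(doc, m$hash, simple_evidence(st))
    after <- mapping_confidence(doc$mappings[[m$hash]], doc)
    expect_gte(after, before)
  }
})

test_that("provenance cycles are detected", {
  set <- mapping_set("s", 0.9)
  doc <- add_mapping_set(mapping_document(), set)
  ha <- mapping_hash("fx1:a", PRED_EXACT, "fx2:b")
  hb <- mapping_hash("fx2:b", PRED_EXACT, "fx1:a")
  ma <- new_mapping("fx1:a", PRED_EXACT, "fx2:b", list(reasoned_evidence("inversion", hb)))
  mb <- new_mapping("fx2:b", PRED_EXACT, "fx1:a", list(reasoned_evidence("inversion", ha)))
  doc <- add_mapping(add_mapping(doc, ma), mb)
  expect_error(mapping_confidence(doc$mappings[[ha]], doc), class = "semmap_provenance_error")
})

test_that("content hashes are deterministic, content-sensitive and triple-scoped", {
  s <- mapping_set("src", 0.5, version = "2", license = "CC0")
  expect_identical(s$hash, mapping_set_hash("src", "2", "CC0"))
  # consumer confidence is not part of a set's content
  expect_identical(mapping_set("src", 0.1, "2", "CC0")$hash, s$hash)
  expect_false(mapping_set("src", 0.5, "3", "CC0")$hash == s$hash)

  m1 <- new_mapping("fx1:a", PRED_EXACT, "fx2:b")
  m2 <- new_mapping("fx1:a", PRED_EXACT, "fx2:b")
  expect_identical(content_hash(m1), content_hash(m2))
  expect_false(new_mapping("fx1:a", PRED_EXACT, "fx2:c")$hash == content_hash(m1))
  # direction matters even for symmetric predicates
  expect_false(mapping_hash("fx2:b", PRED_EXACT, "fx1:a") == m1$hash)

  # mapping identity covers the triple only: evidence accrual keeps the hash
  ev <- simple_evidence(s)
  m3 <- new_mapping("fx1:a", PRED_EXACT, "fx2:b", list(ev))
  expect_identical(content_hash(m3), content_hash(m1))

  # evidence hashes cover full content including the set hash
  e1 <- simple_evidence(s, JUST_MANUAL, "orcid:0000-0000-0000-0001", 0.8)
  e2 <- simple_evidence(s, JUST_MANUAL, "orcid:0000-0000-0000-0001", 0.8)
  expect_identical(e1$hash, e2$hash)
  expect_false(simple_evidence(s, JUST_MANUAL, "orcid:0000-0000-0000-0001", 0.7)$hash == e1$hash)
  other_set <- mapping_set("src2", 0.5)
  expect_false(simple_evidence(other_set, JUST_MANUAL, "orcid:0000-0000-0000-0001", 0.8)$hash == e1$hash)
})

test_that("hashing escapes the field delimiter so distinct content cannot collide", {
  h1 <- mapping_set_hash("a\x1fversion=9", "", "")
  h2 <- mapping_set_hash("a", "9", "")
  expect_false(h1 == h2)
  h3 <- mapping_set_hash("a\\", "x", "")
  h4 <- mapping_set_hash("a", "\\x", "")
  expect_false(h3 == h4)
})

test_that("document merging deduplicates triples and evidence by hash", {
  set <- mapping_set("s", 0.9)
  doc <- add_mapping_set(mapping_document(), set)
  e1 <- simple_evidence(set, JUST_MANUAL)
  e2 <- simple_evidence(set, JUST_UNSPECIFIED)
  doc <- add_mapping(doc, new_mapping("fx1:a", PRED_EXACT, "fx2:b", list(e1)))
  doc <- add_mapping(doc, new_mapping("fx1:a", PRED_EXACT, "fx2:b", list(e2, e1)))
  expect_identical(n_mappings(doc), 1L)
  expect_identical(n_evidences(doc), 2L)
  # directionality: the reverse triple is a distinct mapping
  doc <- add_mapping(doc, new_mapping("fx2:b", PRED_EXACT, "fx1:a", list(e1)))
  expect_identical(n_mappings(doc), 2L)
})
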