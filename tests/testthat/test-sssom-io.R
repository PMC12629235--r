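# SSSOM TSV reading/writing, xref ingestion, property-graph export.

write_lines_tsv <- function(lines, ext = ".sssom.tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("SSSOM rows sharing a triple merge into one mapping with several evidences", {
  path <- write_lines_tsv(c(
    "# mapping_set_name: demo",
    "# mapping_set_confidence: 0.9",
    "subject_id\tpredicate_id\tobject_id\tmapping_justification",
    "fx1:a\tskos:exactMatch\tfx2:b\tsemapv:ManualMappingCuration",
    "fx1:a\tskos:exactMatch\tfx2:b\tsemapv:LexicalMatching",
    "fx1:c\tskos:broadMatch\tfx2:d\tsemapv:ManualMappingCuration"
  ))
  doc <- read_sssom(path)
  expect_identical(n_mappings(doc), 2L)
  expect_identical(n_evidences(doc), 3L)
  m <- doc$mappings[[mapping_hash("fx1:a", PRED_EXACT, "fx2:b")]]
  expect_identical(length(m$evidences), 2L)
  set <- doc$mapping_sets[[m$evidences[[1]]$mapping_set]]
  expect_identical(set$name, "demo")
  expect_identical(set$confidence, 0.9)
})

test_that("an empty SSSOM file with a valid header yields an empty document", {
  path <- write_lines_tsv("subject_id\tpredicate_id\tobject_id\tmapping_justification")
  doc <- read_sssom(path)
  expect_identical(n_mappings(doc), 0L)
})

test_that("missing required columns and bad CURIEs are reported with detail", {
  path <- write_lines_tsv(c(
    "subject_id\tobject_id\tmapping_justification",
    "fx1:a\tfx2:b\tsemapv:ManualMappingCuration"
  ))
  expect_error(read_sssom(path), "predicate_id", class = "semmap_format_error")

  bad <- write_lines_tsv(c(
    "subject_id\tpredicate_id\tobject_id\tmapping_justification",
    "fx1:a\tskos:exactMatch\tfx2:b\tsemapv:ManualMappingCuration",
    "bogus:x\tskos:exactMatch\tfx2:b\tsemapv:ManualMappingCuration"
  ))
  expect_error(read_sssom(bad, strict = TRUE), class = "semmap_curie_error")
  expect_warning(doc <- read_sssom(bad, strict = FALSE))
  expect_identical(n_mappings(doc), 1L)
})

test_that("row-level confidence becomes producer confidence under the set prior", {
  path <- write_lines_tsv(c(
    "subject_id\tpredicate_id\tobject_id\tmapping_justification\tconfidence",
    "fx1:a\tskos:exactMatch\tfx2:b\tsemapv:LexicalMatching\t0.8"
  ))
  doc <- read_sssom(path, set_defaults = list(name = "s"), consumer_confidence = 0.5)
  m <- doc$mappings[[1]]
  # 1 - (1 - 0.5)(1 - 0.8) = 0.9
  expect_equal(mapping_confidence(m, doc), 0.9)
})

test_that("SSSOM round-trips preserve triples, predicates, evidence and confidence", {
  doc <- full_process(toy_cell_line_doc(),
                      mutations = list(mutation_rule(PRED_XREF, PRED_EXACT, factor = 0.7)))
  path <- withr::local_tempfile(fileext = ".sssom.tsv")
  write_sssom(doc, path)
  back <- read_sssom(path, registry = default_registry())
  expect_identical(doc_triples(back)[, c("subject", "predicate", "object")],
                   doc_triples(doc)[, c("subject", "predicate", "object")])
  expect_identical(n_evidences(back), n_evidences(doc))
  expect_equal(unname(document_confidences(back)[names(doc$mappings)]),
               unname(document_confidences(doc)), tolerance = 1e-12)
  # reasoned rows carry the reasoning justification term
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  expect_true(JUST_CHAINING %in% tab$mapping_justification)
  # one row per (mapping, evidence) pair
  expect_identical(nrow(tab), n_evidences(doc))
})

test_that("unknown SSSOM columns pass through a round-trip", {
  path <- write_lines_tsv(c(
    "subject_id\tpredicate_id\tobject_id\tmapping_justification\tcomment_text",
    "fx1:a\tskos:exactMatch\tfx2:b\tsemapv:ManualMappingCuration\thello"
  ))
  doc <- read_sssom(path)
  out <- withr::local_tempfile(fileext = ".sssom.tsv")
  write_sssom(doc, out)
  tab <- readr::read_tsv(out, comment = "#", show_col_types = FALSE)
  expect_identical(tab$comment_text, "hello")
})

test_that("xref TSVs ingest under the declared default predicate and deduplicate", {
  path <- write_lines_tsv(c(
    "fx1:a\tfx2:b",
    "fx1:a\tfx2:b",
    "fx1:c\tfx2:d",
    "fx3:e\tfx2:f"
  ), ext = ".tsv")
  set <- mapping_set("xrefs", 0.7)
  doc <- read_xref_tsv(path, set)
  expect_identical(n_mappings(doc), 3L)
  # duplicated row collapses to one evidence: identical content, same hash
  expect_identical(n_evidences(doc), 3L)
  expect_true(all(doc_triples(doc)$predicate == PRED_XREF))

  expect_message(
    doc2 <- read_xref_tsv(path, set, exclude_prefixes = "fx3"),
    "excluded"
  )
  expect_identical(n_mappings(doc2), 2L)
})

test_that("the property-graph export is referentially closed and count-consistent", {
  doc <- full_process(toy_cell_line_doc(),
                      mutations = list(mutation_rule(PRED_XREF, PRED_EXACT, factor = 0.7)))
  dir <- withr::local_tempdir()
  paths <- export_property_graph(doc, dir)
  read1 <- function(p) readr::read_tsv(p, show_col_types = FALSE,
                                       col_types = readr::cols(.default = readr::col_character()))
  concepts <- read1(paths$nodes_concept)
  mappings <- read1(paths$nodes_mapping)
  evidences <- read1(paths$nodes_evidence)
  sets <- read1(paths$nodes_mapping_set)
  e_map <- read1(paths$edges_mapping)
  e_me <- read1(paths$edges_mapping_evidence)
  e_es <- read1(paths$edges_evidence_mapping_set)
  e_sup <- read1(paths$edges_evidence_support)

  expect_identical(nrow(mappings), n_mappings(doc))
  expect_identical(nrow(e_me), n_evidences(doc))
  # referential closure: every edge endpoint is a known node key
  expect_true(all(e_map$subject %in% concepts$curie))
  expect_true(all(e_map$object %in% concepts$curie))
  expect_true(all(e_map$mapping %in% mappings$hash))
  expect_true(all(e_me$mapping %in% mappings$hash))
  expect_true(all(e_me$evidence %in% evidences$hash))
  expect_true(all(e_es$evidence %in% evidences$hash))
  expect_true(all(e_es$mapping_set %in% sets$hash))
  expect_true(all(e_sup$evidence %in% evidences$hash))
  expect_true(all(e_sup$supports %in% mappings$hash))
  # every mapping node has at least one evidence edge
  expect_setequal(unique(e_me$mapping), mappings$hash)
})

test_that("an empty document exports header-only graph files", {
  dir <- withr::local_tempdir()
  paths <- export_property_graph(mapping_document(), dir)
  tab <- readr::read_tsv(paths$nodes_concept, show_col_types = FALSE)
  expect_identical(nrow(tab), 0L)
})

test_that("reasoned evidence with several supports exports one support edge each", {
  doc <- doc_from_edges(tibble::tibble(
    subject = c("fx1:a", "fx2:b"), predicate = PRED_EXACT,
    object = c("fx2:b", "fx3:c")
  ))
  h1 <- mapping_hash("fx1:a", PRED_EXACT, "fx2:b")
  h2 <- mapping_hash("fx2:b", PRED_EXACT, "fx3:c")
  ev <- reasoned_evidence("chain", c(h1, h2))
  doc <- add_mapping(doc, new_mapping("fx1:a", PRED_EXACT, "fx3:c", list(ev)))
  dir <- withr::local_tempdir()
  paths <- export_property_graph(doc, dir)
  e_sup <- readr::read_tsv(paths$edges_evidence_support, show_col_types = FALSE)
  expect_identical(nrow(e_sup), 2L)
})
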