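#' Property-graph file export
#'
#' Serializes a mapping document into a directory of node and edge TSVs, the
#' layout a property-graph database bulk loader consumes. Concepts, mappings,
#' evidences and mapping sets are all nodes (mappings appear both as nodes and
#' as concept-to-concept edges, which keeps both traversal styles queryable);
#' edges record mapping-to-evidence, evidence-to-mapping-set and
#' reasoned-evidence-to-supporting-mapping interdependencies.
#'
#' Files written: `nodes_concept.tsv` (curie, prefix), `nodes_mapping.tsv`
#' (hash, subject, predicate, object, confidence), `nodes_evidence.tsv`
#' (hash, type, justification, confidence), `nodes_mapping_set.tsv`
#' (hash, name, version, license, confidence), `edges_mapping.tsv`
#' (subject, object, predicate, mapping), `edges_mapping_evidence.tsv`
#' (mapping, evidence), `edges_evidence_mapping_set.tsv` (evidence,
#' mapping_set), `edges_evidence_support.tsv` (evidence, supporting mapping),
#' and `metadata.json` (hash algorithm, counts).
#'
#' @param doc A `mapping_document`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named list of the written file paths.
#' @export
export_property_graph <- function(doc, out_dir) {
  doc <- sort_document(doc)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  confs <- document_confidences(doc)
  ms <- doc$mappings

  chrcol <- function(f) vapply(ms, f, character(1), USE.NAMES = FALSE)
  subjects <- chrcol(function(m) m$subject)
  objects <- chrcol(function(m) m$object)
  concepts <- sort(unique(c(subjects, objects)))

  nodes_concept <- tibble::tibble(curie = concepts, prefix = curie_prefix(concepts))
  nodes_mapping <- tibble::tibble(
    hash = chrcol(function(m) m$hash),
    subject = subjects,
    predicate = chrcol(function(m) m$predicate),
    object = objects,
    confidence = unname(confs)
  )
  ev_rows <- list(); me_rows <- list(); es_rows <- list(); sup_rows <- list()
  memo <- new.env(parent = emptyenv())
  for (m in ms) {
    for (e in m$evidences) {
      ev_rows[[e$hash]] <- tibble::tibble(
        hash = e$hash, type = e$type, justification = e$justification,
        confidence = evidence_confidence(e, doc, .memo = memo)
      )
      me_rows[[length(me_rows) + 1L]] <- tibble::tibble(mapping = m$hash, evidence = e$hash)
      if (e$type == "simple") {
        es_rows[[length(es_rows) + 1L]] <- tibble::tibble(evidence = e$hash, mapping_set = e$mapping_set)
      } else {
        sup_rows[[length(sup_rows) + 1L]] <- tibble::tibble(evidence = e$hash, supports = e$supports)
      }
    }
  }
  bind <- function(rows, proto) {
    if (length(rows)) dplyr::bind_rows(rows) else proto
  }
  if (length(ev_rows)) ev_rows <- ev_rows[order(names(ev_rows), method = "radix")]
  nodes_evidence <- bind(ev_rows,
                         tibble::tibble(hash = character(), type = character(),
                                        justification = character(), confidence = numeric()))
  nodes_set <- if (length(doc$mapping_sets)) {
    dplyr::bind_rows(lapply(doc$mapping_sets, function(s) {
      tibble::tibble(hash = s$hash, name = s$name, version = s$version,
                     license = s$license, confidence = s$confidence)
    }))
  } else {
    tibble::tibble(hash = character(), name = character(), version = character(),
                   license = character(), confidence = numeric())
  }
  edges_mapping <- tibble::tibble(subject = subjects, object = objects,
                                  predicate = nodes_mapping$predicate,
                                  mapping = nodes_mapping$hash)
  edges_me <- bind(me_rows, tibble::tibble(mapping = character(), evidence = character()))
  edges_es <- bind(es_rows, tibble::tibble(evidence = character(), mapping_set = character()))
  edges_sup <- bind(sup_rows, tibble::tibble(evidence = character(), supports = character()))

  paths <- list(
    nodes_concept = file.path(out_dir, "nodes_concept.tsv"),
    nodes_mapping = file.path(out_dir, "nodes_mapping.tsv"),
    nodes_evidence = file.path(out_dir, "nodes_evidence.tsv"),
    nodes_mapping_set = file.path(out_dir, "nodes_mapping_set.tsv"),
    edges_mapping = file.path(out_dir, "edges_mapping.tsv"),
    edges_mapping_evidence = file.path(out_dir, "edges_mapping_evidence.tsv"),
    edges_evidence_mapping_set = file.path(out_dir, "edges_evidence_mapping_set.tsv"),
    edges_evidence_support = file.path(out_dir, "edges_evidence_support.tsv"),
    metadata = file.path(out_dir, "metadata.json")
  )
  readr::write_tsv(nodes_concept, paths$nodes_concept)
  readr::write_tsv(nodes_mapping, paths$nodes_mapping)
  readr::write_tsv(nodes_evidence, paths$nodes_evidence)
  readr::write_tsv(nodes_set, paths$nodes_mapping_set)
  readr::write_tsv(edges_mapping, paths$edges_mapping)
  readr::write_tsv(edges_me, paths$edges_mapping_evidence)
  readr::write_tsv(edges_es, paths$edges_evidence_mapping_set)
  readr::write_tsv(edges_sup, paths$edges_evidence_support)
  jsonlite::write_json(
    list(hash_algorithm = HASH_ALGORITHM,
         n_concepts = nrow(nodes_concept), n_mappings = nrow(nodes_mapping),
         n_evidences = nrow(nodes_evidence), n_mapping_sets = nrow(nodes_set)),
    paths$metadata, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
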