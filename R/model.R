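#' Mapping data model
#'
#' A mapping document holds a collection of unique mapping triples, each
#' carrying one or more evidence objects, together with the registry of mapping
#' sets the evidence cites and a prefix map covering every CURIE prefix in use.
#' Triples are unique: ingesting a duplicate triple merges its evidence onto
#' the existing mapping rather than duplicating it. Directionality is explicit:
#' `(A, p, B)` and `(B, p, A)` are distinct mappings even for symmetric `p`.
#'
#' @name mapping-model
NULL

#' Create a mapping set
#'
#' A mapping set is a named, versioned, licensed source of mappings together
#' with the *consumer's* confidence in it — the prior probability, from the
#' point of view of whoever is assembling mappings, that an arbitrary mapping
#' taken from this set is correct.
#'
#' @param name Source name (non-empty).
#' @param confidence Consumer confidence in `[0, 1]`.
#' @param version,license Optional strings (may be empty).
#' @return A `semmap_mapping_set`.
#' @export
#' @examples
#' mapping_set("toy-source", 0.9)
mapping_set <- function(name, confidence, version = "", license = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_unit_interval(confidence, "confidence")
  structure(
    list(name = name, version = version %||% "", license = license %||% "",
         confidence = confidence,
         hash = mapping_set_hash(name, version %||% "", license %||% "")),
    class = "semmap_mapping_set"
  )
}

check_unit_interval <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s", what,
                  paste(format(x), collapse = ", ")),
          class = "semmap_domain_error")
  }
  invisible(x)
}

#' Create a simple (provenance-leaf) evidence object
#'
#' @param mapping_set A `semmap_mapping_set` or its content hash.
#' @param justification Mapping-justification CURIE (semantic mapping
#'   vocabulary term), e.g. `"semapv:ManualMappingCuration"`.
#' @param author Optional ORCID-form CURIE (`"orcid:..."`), or `NA`.
#' @param confidence Optional producer confidence in `[0, 1]`, or `NA` when the
#'   producer published none. Absence is modelled explicitly, not as 0 or 1.
#' @return A `semmap_evidence` with `type = "simple"`.
#' @export
simple_evidence <- function(mapping_set, justification = JUST_UNSPECIFIED,
                            author = NA_character_, confidence = NA_real_) {
  set_hash <- if (inherits(mapping_set, "semmap_mapping_set")) mapping_set$hash else mapping_set
  stopifnot(is.character(set_hash), length(set_hash) == 1L)
  if (!is.na(confidence)) check_unit_interval(confidence, "confidence")
  structure(
    list(type = "simple", justification = justification,
         author = author %||% NA_character_, confidence = confidence,
         mapping_set = set_hash,
         hash = simple_evidence_hash(justification, author %||% NA_character_,
                                     confidence, set_hash)),
    class = "semmap_evidence"
  )
}

#' Create a reasoned (inference) evidence object
#'
#' Reasoned evidence points at the mappings an inference operation consumed.
#' `factor` is the operation-specific scaling `gamma` applied on top of the
#' noisy-OR of the supporting mappings' confidences. `support_confidence` is a
#' snapshot of that noisy-OR taken when the evidence was created; it keeps the
#' evidence's confidence computable if a later filter removes a supporting
#' mapping from the document. Live recomputation over the provenance DAG is
#' authoritative whenever all supports still resolve.
#'
#' @param operation One of `"inversion"`, `"mutation"`, `"chain"`,
#'   `"prioritization"`.
#' @param supports Ordered character vector (length >= 1) of supporting mapping
#'   hashes.
#' @param factor Operation scaling factor in `[0, 1]`.
#' @param justification Mapping-justification CURIE; defaults per operation.
#' @param support_confidence Optional snapshot of the noisy-OR over supports.
#' @return A `semmap_evidence` with `type = "reasoned"`.
#' @export
reasoned_evidence <- function(operation, supports, factor = 1,
                              justification = NULL,
                              support_confidence = NA_real_) {
  stopifnot(is.character(supports), length(supports) >= 1L)
  check_unit_interval(factor, "factor")
  operation <- match.arg(operation, c("inversion", "mutation", "chain", "prioritization"))
  if (is.null(justification)) {
    justification <- switch(operation,
      inversion = JUST_INVERSION, mutation = JUST_MUTATION,
      chain = JUST_CHAINING, prioritization = JUST_PRIORITIZATION)
  }
  structure(
    list(type = "reasoned", justification = justification, operation = operation,
         factor = factor, supports = supports,
         support_confidence = support_confidence,
         hash = reasoned_evidence_hash(justification, operation, factor, supports)),
    class = "semmap_evidence"
  )
}

#' Create a mapping (a unique subject-predicate-object triple)
#'
#' @param subject,object Normalized CURIE strings.
#' @param predicate Predicate CURIE from the active vocabulary.
#' @param evidences List of `semmap_evidence` objects (may be empty at
#'   construction; a mapping must carry at least one evidence by the time it
#'   enters a document).
#' @return A `semmap_mapping`.
#' @export
new_mapping <- function(subject, predicate, object, evidences = list()) {
  ev <- list()
  for (e in evidences) ev[[e$hash]] <- e
  structure(
    list(subject = subject, predicate = predicate, object = object,
         evidences = ev, hash = mapping_hash(subject, predicate, object)),
    class = "semmap_mapping"
  )
}

#' Create an empty mapping document
#'
#' @param mappings Named list of `semmap_mapping`, keyed by triple hash.
#' @param mapping_sets Named list of `semmap_mapping_set`, keyed by set hash.
#' @param prefix_map Named character vector, prefix -> URI prefix.
#' @return A `mapping_document`.
#' @export
mapping_document <- function(mappings = list(), mapping_sets = list(),
                             prefix_map = character()) {
  structure(
    list(mappings = mappings, mapping_sets = mapping_sets, prefix_map = prefix_map),
    class = "mapping_document"
  )
}

#' @export
print.mapping_document <- function(x, ...) {
  cat(sprintf("<mapping_document> %d mapping(s), %d evidence(s), %d mapping set(s), %d prefix(es)\n",
              n_mappings(x), n_evidences(x), length(x$mapping_sets), length(x$prefix_map)))
  invisible(x)
}

#' Number of mappings / evidences in a document
#' @param doc A `mapping_document`.
#' @return Integer count.
#' @export
n_mappings <- function(doc) length(doc$mappings)

#' @rdname n_mappings
#' @export
n_evidences <- function(doc) {
  if (!length(doc$mappings)) return(0L)
  sum(vapply(doc$mappings, function(m) length(m$evidences), integer(1)))
}

#' Register a mapping set in a document
#' @param doc A `mapping_document`.
#' @param set A `semmap_mapping_set`.
#' @return The updated document.
#' @export
add_mapping_set <- function(doc, set) {
  stopifnot(inherits(set, "semmap_mapping_set"))
  doc$mapping_sets[[set$hash]] <- set
  doc
}

#' Add a mapping to a document, merging evidence on duplicate triples
#'
#' @param doc A `mapping_document`.
#' @param mapping A `semmap_mapping`.
#' @return The updated document: if the triple already exists its evidence set
#'   is the union (by evidence hash) of old and new; the triple is never
#'   duplicated.
#' @export
add_mapping <- function(doc, mapping) {
  stopifnot(inherits(mapping, "semmap_mapping"))
  h <- mapping$hash
  existing <- doc$mappings[[h]]
  if (is.null(existing)) {
    doc$mappings[[h]] <- mapping
  } else {
    for (e in mapping$evidences) existing$evidences[[e$hash]] <- e
    doc$mappings[[h]] <- existing
  }
  doc
}

#' Attach an evidence object to an existing mapping
#' @param doc A `mapping_document`.
#' @param mapping_hash Triple hash of the target mapping.
#' @param evidence A `semmap_evidence`.
#' @return The updated document.
#' @export
add_evidence <- function(doc, mapping_hash, evidence) {
  m <- doc$mappings[[mapping_hash]]
  if (is.null(m)) abort("No mapping with that hash in the document", class = "semmap_provenance_error")
  m$evidences[[evidence$hash]] <- evidence
  doc$mappings[[mapping_hash]] <- m
  doc
}

#' Merge several mapping documents into one
#'
#' Triples occurring in more than one document merge their evidence; mapping
#' sets and prefix maps take the union.
#'
#' @param docs List of `mapping_document`s.
#' @return A single merged `mapping_document`.
#' @export
merge_documents <- function(docs) {
  out <- mapping_document()
  for (doc in docs) {
    for (s in doc$mapping_sets) out <- add_mapping_set(out, s)
    for (m in doc$mappings) out <- add_mapping(out, m)
    out$prefix_map <- c(out$prefix_map, doc$prefix_map[setdiff(names(doc$prefix_map), names(out$prefix_map))])
  }
  sort_document(out)
}

#' Put a document into canonical (deterministic) order
#'
#' Mappings are ordered lexicographically by (subject, predicate, object);
#' evidences within each mapping and mapping sets by their content hash;
#' the prefix map alphabetically. All exports and inference passes iterate in
#' this order, so repeated runs are byte-identical.
#'
#' @param doc A `mapping_document`.
#' @return The reordered document.
#' @export
sort_document <- function(doc) {
  if (length(doc$mappings)) {
    key <- vapply(doc$mappings, function(m) paste(m$subject, m$predicate, m$object, sep = "\x1f"),
                  character(1))
    doc$mappings <- doc$mappings[order(key, method = "radix")]
    doc$mappings <- lapply(doc$mappings, function(m) {
      m$evidences <- m$evidences[order(names(m$evidences), method = "radix")]
      m
    })
  }
  if (length(doc$mapping_sets)) {
    doc$mapping_sets <- doc$mapping_sets[order(names(doc$mapping_sets), method = "radix")]
  }
  if (length(doc$prefix_map)) {
    doc$prefix_map <- doc$prefix_map[order(names(doc$prefix_map), method = "radix")]
  }
  doc
}

#' Tabulate a document's triples
#'
#' @param doc A `mapping_document`.
#' @return A tibble with one row per mapping: `hash`, `subject`, `predicate`,
#'   `object`, `n_evidences`.
#' @export
doc_triples <- function(doc) {
  ms <- doc$mappings
  tibble::tibble(
    hash = vapply(ms, `[[`, character(1), "hash", USE.NAMES = FALSE),
    subject = vapply(ms, `[[`, character(1), "subject", USE.NAMES = FALSE),
    predicate = vapply(ms, `[[`, character(1), "predicate", USE.NAMES = FALSE),
    object = vapply(ms, `[[`, character(1), "object", USE.NAMES = FALSE),
    n_evidences = vapply(ms, function(m) length(m$evidences), integer(1), USE.NAMES = FALSE)
  )
}

#' Build a document from a row-per-evidence table
#'
#' Workhorse behind the readers and the fixture generator. Rows sharing a
#' triple merge into one mapping with several evidences; identical evidence
#' content deduplicates by hash.
#'
#' @param rows Tibble/data.frame with columns `subject`, `predicate`, `object`
#'   (normalized CURIEs), `justification`, `author`, `confidence` (producer
#'   confidence, `NA` allowed) and `mapping_set` (set hash).
#' @param mapping_sets List of `semmap_mapping_set` covering every hash cited.
#' @param registry Registry used to build the prefix map for all used prefixes.
#' @return A sorted `mapping_document`.
#' @export
document_from_rows <- function(rows, mapping_sets, registry = default_registry()) {
  doc <- mapping_document()
  for (s in mapping_sets) doc <- add_mapping_set(doc, s)
  if (nrow(rows)) {
    hashes <- mapping_hash(rows$subject, rows$predicate, rows$object)
    grp <- split(seq_len(nrow(rows)), hashes)
    mappings <- lapply(grp, function(idx) {
      evs <- lapply(idx, function(i) {
        simple_evidence(rows$mapping_set[[i]], rows$justification[[i]],
                        rows$author[[i]], rows$confidence[[i]])
      })
      new_mapping(rows$subject[[idx[1]]], rows$predicate[[idx[1]]],
                  rows$object[[idx[1]]], evs)
    })
    doc$mappings <- mappings
  }
  doc$prefix_map <- prefix_map_for(
    unique(curie_prefix(c(rows$subject, rows$object))), registry)
  sort_document(doc)
}

#' Validate a document's structural invariants
#'
#' Checks that every mapping has at least one evidence, every simple evidence's
#' mapping set resolves, every reasoned evidence's supports resolve (unless it
#' carries a snapshot confidence), the provenance graph is acyclic, and every
#' used prefix appears in the prefix map.
#'
#' @param doc A `mapping_document`.
#' @return Invisibly `TRUE`; errors with a message on the first violation.
#' @export
validate_document <- function(doc) {
  for (m in doc$mappings) {
    if (!length(m$evidences)) {
      abort(sprintf("Mapping %s -> %s has no evidence", m$subject, m$object),
            class = "semmap_invariant_error")
    }
    for (e in m$evidences) {
      if (e$type == "simple" && is.null(doc$mapping_sets[[e$mapping_set]])) {
        abort(sprintf("Evidence on %s -> %s cites an unregistered mapping set",
                      m$subject, m$object), class = "semmap_provenance_error")
      }
      if (e$type == "reasoned" && is.na(e$support_confidence)) {
        missing <- setdiff(e$supports, names(doc$mappings))
        if (length(missing)) {
          abort(sprintf("Reasoned evidence on %s -> %s cites %d missing support(s)",
                        m$subject, m$object, length(missing)),
                class = "semmap_provenance_error")
        }
      }
    }
  }
  used <- unique(curie_prefix(c(
    vapply(doc$mappings, `[[`, character(1), "subject", USE.NAMES = FALSE),
    vapply(doc$mappings, `[[`, character(1), "object", USE.NAMES = FALSE)
  )))
  missing <- setdiff(used, names(doc$prefix_map))
  if (length(missing)) {
    abort(sprintf("Prefixes missing from prefix map: %s", paste(missing, collapse = ", ")),
          class = "semmap_invariant_error")
  }
  document_confidences(doc)  # errors on provenance cycles
  invisible(TRUE)
}
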