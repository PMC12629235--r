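#' Graph inference over mapping documents
#'
#' The document's mappings form a directed multigraph (subject -> object,
#' parallel edges allowed for distinct predicates). Three inference operations
#' add edges, each recording its provenance as reasoned evidence on the new
#' mapping:
#'
#' * **inversion** adds the reverse edge under the inverse predicate,
#' * **mutation** adds a parallel edge under a replacement predicate
#'   (generalizing, e.g. class-equivalence to exact match, or strengthening,
#'   e.g. cross-reference to exact match, under explicitly configured rules),
#' * **chaining** adds an edge for every predicate-composable path of length
#'   2..`max_path_length`.
#'
#' All passes iterate in canonical document order so outputs are byte-stable.
#'
#' @name inference
NULL

sorted_hashes <- function(doc) {
  key <- vapply(doc$mappings, function(m) paste(m$subject, m$predicate, m$object, sep = "\x1f"),
                character(1))
  names(doc$mappings)[order(key, method = "radix")]
}

#' Infer inverse mappings
#'
#' For every mapping `(A, p, B)` whose counterpart `(B, inv(p), A)` is absent,
#' adds the counterpart carrying reasoned evidence (operation `"inversion"`,
#' the original mapping as single support). Existing counterparts gain nothing,
#' so a second pass is a fixpoint.
#'
#' @param doc A `mapping_document`.
#' @param vocabulary Predicate vocabulary; every predicate in the document must
#'   declare an inverse there.
#' @param factor Scaling factor for inversion evidence; inversion is lossless
#'   logic, so the default is 1.
#' @return The augmented document.
#' @export
infer_inversions <- function(doc, vocabulary = default_vocabulary(), factor = 1) {
  snapshot <- sorted_hashes(doc)
  memo <- new.env(parent = emptyenv())
  for (h in snapshot) {
    m <- doc$mappings[[h]]
    inv_pred <- invert_predicate(m$predicate, vocabulary)
    inv_hash <- mapping_hash(m$object, inv_pred, m$subject)
    if (!is.null(doc$mappings[[inv_hash]])) next
    snap <- mapping_confidence(m, doc, .memo = memo)
    ev <- reasoned_evidence("inversion", supports = h, factor = factor,
                            support_confidence = snap)
    doc <- add_mapping(doc, new_mapping(m$object, inv_pred, m$subject, list(ev)))
  }
  sort_document(doc)
}

#' Create a predicate mutation rule
#'
#' @param source,target Predicate CURIEs: edges carrying `source` gain a
#'   parallel edge carrying `target`.
#' @param factor Confidence scaling in `[0, 1]` for the mutation evidence.
#'   Generalizations (weakening, e.g. equivalence to exact match) default to 1;
#'   strengthenings (e.g. cross-reference to exact match) encode a real
#'   epistemic risk and must be given explicitly.
#' @param subject_prefix,object_prefix Optional scope: the rule fires only on
#'   edges whose subject/object prefix matches.
#' @return A `mutation_rule`.
#' @export
#' @examples
#' mutation_rule("owl:equivalentClass", "skos:exactMatch")
#' mutation_rule("oboinowl:hasDbXref", "skos:exactMatch", factor = 0.7)
mutation_rule <- function(source, target, factor = 1,
                          subject_prefix = NULL, object_prefix = NULL) {
  check_unit_interval(factor, "factor")
  structure(
    list(source = source, target = target, factor = factor,
         subject_prefix = subject_prefix, object_prefix = object_prefix),
    class = "mutation_rule"
  )
}

#' Apply predicate mutation rules
#'
#' Each mapping matching a rule's source predicate (and prefix scope, if any)
#' gains a parallel mapping with the target predicate, carrying reasoned
#' evidence (operation `"mutation"`, `gamma` = the rule's factor, single
#' support). If the target triple already exists the evidence merges onto it.
#'
#' @param doc A `mapping_document`.
#' @param rules List of [mutation_rule()]s, applied in order.
#' @param vocabulary Predicate vocabulary; rules must reference known
#'   predicates.
#' @return The augmented document.
#' @export
apply_mutations <- function(doc, rules, vocabulary = default_vocabulary()) {
  if (!length(rules)) return(doc)
  for (r in rules) {
    if (!all(c(r$source, r$target) %in% vocabulary$predicate)) {
      abort(sprintf("Mutation rule references unknown predicate(s): %s -> %s",
                    r$source, r$target), class = "semmap_config_error")
    }
  }
  memo <- new.env(parent = emptyenv())
  for (r in rules) {
    snapshot <- sorted_hashes(doc)
    for (h in snapshot) {
      m <- doc$mappings[[h]]
      if (!identical(m$predicate, r$source)) next
      if (!is.null(r$subject_prefix) && curie_prefix(m$subject) != r$subject_prefix) next
      if (!is.null(r$object_prefix) && curie_prefix(m$object) != r$object_prefix) next
      snap <- mapping_confidence(m, doc, .memo = memo)
      ev <- reasoned_evidence("mutation", supports = h, factor = r$factor,
                              support_confidence = snap)
      doc <- add_mapping(doc, new_mapping(m$subject, r$target, m$object, list(ev)))
    }
  }
  sort_document(doc)
}

negative_hashes <- function(negatives) {
  if (is.null(negatives)) return(character())
  if (is.character(negatives)) return(negatives)
  if (is.data.frame(negatives)) {
    if (!nrow(negatives)) return(character())
    return(mapping_hash(negatives$subject, negatives$predicate, negatives$object))
  }
  abort("`negatives` must be NULL, a character vector of triple hashes, or a data frame with subject/predicate/object columns",
        class = "semmap_config_error")
}

#' Infer transitive chain mappings
#'
#' Depth-first traversal of the directed mapping graph from every node (in
#' lexicographic CURIE order), composing predicates along simple paths (no
#' node revisited) of length 2..`max_path_length` under the chain-rule table.
#' A path whose running composition yields nothing stops extending (composing
#' with nothing is absorbing). For every composed triple not already present
#' as a direct mapping, one mapping is added; each distinct supporting path
#' contributes its own reasoned evidence (operation `"chain"`, the path's
#' mappings as ordered supports, `gamma` = `factor`), so confidence is
#' independent of path discovery order. Paths are never allowed to step
#' through a triple listed in `negatives`.
#'
#' Run [infer_inversions()] first: traversal follows directed edges only, and
#' inversion is what makes symmetric structure visible in both directions.
#'
#' @param doc A `mapping_document`.
#' @param rules Chain-rule table, see [default_chain_rules()].
#' @param max_path_length Maximum path length (edges) to compose; must be >= 2.
#' @param negatives Triples to exclude as chain steps: a data frame with
#'   `subject`/`predicate`/`object`, a character vector of triple hashes, or
#'   `NULL`.
#' @param factor Scaling factor `gamma` for chain evidence (default 1: the
#'   step confidences already combine through the noisy-OR over supports).
#' @return The augmented document.
#' @export
infer_chains <- function(doc, rules = default_chain_rules(), max_path_length = 5,
                         negatives = NULL, factor = 1) {
  if (!is.numeric(max_path_length) || max_path_length < 2) {
    abort("`max_path_length` must be at least 2", class = "semmap_config_error")
  }
  idx <- chain_rule_index(rules)
  neg <- negative_hashes(negatives)
  edge_hashes <- sorted_hashes(doc)
  edge_hashes <- setdiff(edge_hashes, neg)

  adj <- new.env(parent = emptyenv())
  for (h in edge_hashes) {
    m <- doc$mappings[[h]]
    lst <- get0(m$subject, envir = adj, ifnotfound = list())
    lst[[length(lst) + 1L]] <- list(to = m$object, pred = m$predicate, hash = h)
    assign(m$subject, lst, envir = adj)
  }

  existing <- names(doc$mappings)
  found <- new.env(parent = emptyenv())  # triple hash -> list(subject, predicate, object, paths)

  walk <- function(start, node, pred, path, on_path) {
    nbrs <- get0(node, envir = adj, ifnotfound = NULL)
    if (is.null(nbrs)) return()
    for (nb in nbrs) {
      if (isTRUE(get0(nb$to, envir = on_path, ifnotfound = FALSE))) next
      composed <- get0(paste(pred, nb$pred, sep = "|"), envir = idx, ifnotfound = NA_character_)
      if (is.na(composed)) next
      new_path <- c(path, nb$hash)
      if (length(new_path) >= 2L) {
        th <- mapping_hash(start, composed, nb$to)
        if (!(th %in% existing)) {
          rec <- get0(th, envir = found,
                      ifnotfound = list(subject = start, predicate = composed,
                                        object = nb$to, paths = list()))
          rec$paths[[length(rec$paths) + 1L]] <- new_path
          assign(th, rec, envir = found)
        }
      }
      if (length(new_path) < max_path_length) {
        on_path[[nb$to]] <- TRUE
        walk(start, nb$to, composed, new_path, on_path)
        on_path[[nb$to]] <- FALSE
      }
    }
  }

  starts <- sort(unique(vapply(edge_hashes, function(h) doc$mappings[[h]]$subject,
                               character(1), USE.NAMES = FALSE)))
  for (s in starts) {
    on_path <- new.env(parent = emptyenv())
    on_path[[s]] <- TRUE
    nbrs <- get0(s, envir = adj, ifnotfound = NULL)
    for (nb in nbrs) {
      if (identical(nb$to, s)) next
      on_path[[nb$to]] <- TRUE
      walk(s, nb$to, nb$pred, nb$hash, on_path)
      on_path[[nb$to]] <- FALSE
    }
  }

  memo <- new.env(parent = emptyenv())
  inferred <- mget(ls(found, sorted = TRUE), envir = found)
  for (rec in inferred) {
    if (identical(rec$subject, rec$object)) next
    evs <- lapply(rec$paths, function(p) {
      snap <- noisy_or(vapply(p, function(ph) {
        mapping_confidence(doc$mappings[[ph]], doc, .memo = memo)
      }, numeric(1)))
      reasoned_evidence("chain", supports = p, factor = factor,
                        support_confidence = snap)
    })
    doc <- add_mapping(doc, new_mapping(rec$subject, rec$predicate, rec$object, evs))
  }
  sort_document(doc)
}

#' Run the full processing sequence on a document
#'
#' Applies, in the configured stage order (default: mutations, inversions,
#' chaining, filters), the three inference operations and the filter rules,
#' recording per-stage mapping counts in a processing log attached to the
#' result as attribute `"processing_log"`.
#'
#' @param doc A `mapping_document`.
#' @param mutations List of [mutation_rule()]s (may be empty).
#' @param inversions Logical: run inversion inference.
#' @param chains `NULL` to skip chaining, or a list with optional elements
#'   `max_path_length`, `factor`, `rules` (chain-rule table).
#' @param filters List of filter rules (see [filter_rule()]), applied in order.
#' @param negatives Negative triples (data frame or hash vector): removed from
#'   the document and excluded as chain steps.
#' @param vocabulary Predicate vocabulary.
#' @param stage_order Character vector ordering of
#'   `c("mutations", "inversions", "chains", "filters")`.
#' @return The processed document, with attributes `"processing_log"` (tibble
#'   of per-stage counts) and `"removed"` (tibble of filtered mappings).
#' @export
full_process <- function(doc, mutations = list(), inversions = TRUE, chains = list(),
                         filters = list(), negatives = NULL,
                         vocabulary = default_vocabulary(),
                         stage_order = c("mutations", "inversions", "chains", "filters")) {
  stage_order <- match.arg(stage_order, several.ok = TRUE)
  log <- list(tibble::tibble(stage = "input", n_mappings = n_mappings(doc),
                             n_evidences = n_evidences(doc)))
  removed_all <- list()
  if (!is.null(negatives)) {
    doc <- apply_negatives(doc, negatives)
    log[[length(log) + 1L]] <- tibble::tibble(stage = "negatives", n_mappings = n_mappings(doc),
                                              n_evidences = n_evidences(doc))
  }
  for (stage in stage_order) {
    if (stage == "mutations" && length(mutations)) {
      doc <- apply_mutations(doc, mutations, vocabulary)
    } else if (stage == "inversions" && isTRUE(inversions)) {
      doc <- infer_inversions(doc, vocabulary)
    } else if (stage == "chains" && !is.null(chains)) {
      doc <- infer_chains(doc,
                          rules = chains$rules %||% default_chain_rules(),
                          max_path_length = chains$max_path_length %||% 5,
                          negatives = negatives,
                          factor = chains$factor %||% 1)
    } else if (stage == "filters" && length(filters)) {
      for (fr in filters) {
        res <- apply_filter(doc, fr)
        doc <- res$doc
        if (nrow(res$removed)) removed_all[[length(removed_all) + 1L]] <- res$removed
      }
    } else {
      next
    }
    log[[length(log) + 1L]] <- tibble::tibble(stage = stage, n_mappings = n_mappings(doc),
                                              n_evidences = n_evidences(doc))
  }
  doc <- sort_document(doc)
  attr(doc, "processing_log") <- dplyr::bind_rows(log)
  attr(doc, "removed") <- if (length(removed_all)) dplyr::bind_rows(removed_all) else empty_removed()
  doc
}
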